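#' Configuration of the synthetic-data generator
#'
#' The generator emulates Tapestri-style targeted panel data: a small
#' number of gene-level regions with markedly unequal amplification
#' efficiencies, overdispersed per-region read depths, allele-specific
#' dropout, sequencing error, doublets and Dirichlet-distributed clone
#' sizes.  Defaults follow the scale of a typical recovery experiment:
#' 3000 cells, 30 regions, 6-node trees, Dirichlet concentration 0.3 (the
#' value typical of real clone-size imbalance), non-uniform coverage.
#'
#' @param n_cells,n_regions,n_nodes,n_snvs,n_cnas problem dimensions;
#'   `n_snvs` counts somatic SNVs (at least `n_nodes - 1` so every clone
#'   carries an event), `n_nodes >= 1` (a single node simulates a pure
#'   normal population carrying only germline SNPs).
#' @param concentration Dirichlet concentration of the node weights; small
#'   values give unequal clone sizes.
#' @param coverage_mode `"uniform"` or `"nonuniform"` amplicon efficiency.
#' @param coverage_sigma log-normal spread of region efficiencies in
#'   non-uniform mode.
#' @param depth_mean expected reads per amplicon per cell (Tapestri
#'   panels typically sequence 30-80x per amplicon); the expected total
#'   cell depth is `depth_mean` times the panel's amplicon count.
#' @param theta negative-binomial inverse dispersion of region depths.
#' @param eps sequencing error rate.
#' @param dropout_mean,dropout_sd centre and spread of the per-variant
#'   dropout rates.
#' @param doublet_rate fraction of barcodes containing two cells.
#' @param coverage_correlation `"off"` or `"on"`: when on, a per-cell
#'   binary latent factor multiplicatively tilts a fixed random half of
#'   the regions, creating block-correlated depth fractions.
#' @param correlation_gamma tilt magnitude of the latent factor.
#' @param fraction_germline germline SNPs added at the root, as a fraction
#'   of `n_snvs` (rounded).
#' @param n_germline explicit germline SNP count overriding
#'   `fraction_germline` (needed e.g. for somatic-event-free simulations).
#' @param snv_support_fraction fraction of simulated CNAs required to be
#'   supported by an SNV or LOH at or below their node.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 3000, n_regions = 30, n_nodes = 6,
                       n_snvs = 7, n_cnas = 3, concentration = 0.3,
                       coverage_mode = c("nonuniform", "uniform"),
                       coverage_sigma = 1, depth_mean = 40, theta = 6,
                       eps = 0.01, dropout_mean = 0.05, dropout_sd = 0.02,
                       doublet_rate = 0.05,
                       coverage_correlation = c("off", "on"),
                       correlation_gamma = 0.3, fraction_germline = 0.5,
                       n_germline = NULL, snv_support_fraction = 1) {
  coverage_mode <- match.arg(coverage_mode)
  coverage_correlation <- match.arg(coverage_correlation)
  stopifnot(n_nodes >= 1, n_cells >= 1, n_regions >= 2, concentration > 0,
            n_snvs + n_cnas >= n_nodes - 1,
            depth_mean > 0, theta > 0, doublet_rate >= 0, doublet_rate < 1)
  structure(as.list(environment()), class = "sim_config")
}

# variant/region metadata scaffold for a simulated panel
sim_metadata <- function(config) {
  nr <- config$n_regions
  chrom <- paste0("chr", 1 + (seq_len(nr) - 1) %/% 3)
  order_index <- stats::ave(seq_len(nr), chrom, FUN = seq_along)
  n_amp <- sample(1:4, nr, replace = TRUE)
  regions <- data.frame(id = paste0("GENE", seq_len(nr)), chrom = chrom,
                        order_index = order_index, n_amplicons = n_amp,
                        usable_for_cna = TRUE)
  n_germ <- config$n_germline %||%
    round(config$fraction_germline * config$n_snvs)
  nv <- config$n_snvs + n_germ
  if (nv < 1L) { nv <- 1L; n_germ <- 1L } # at least one (germline) locus
  reg_of <- sample.int(nr, nv, replace = TRUE)
  # a variant occupies one amplicon; make sure its region has room
  for (k in unique(reg_of)) {
    need <- sum(reg_of == k)
    if (regions$n_amplicons[k] < need) regions$n_amplicons[k] <- need
  }
  is_germ <- rep(FALSE, nv)
  if (n_germ > 0L) is_germ[sample.int(nv, n_germ)] <- TRUE
  if (config$n_snvs == 0L) is_germ[] <- TRUE
  variants <- data.frame(
    id = paste0("var", seq_len(nv)), region = reg_of,
    chrom = regions$chrom[reg_of],
    pos = 1000L * seq_len(nv),
    pop_freq = ifelse(is_germ, round(runif(nv, 0.05, 0.5), 3), NA_real_))
  list(regions = regions, variants = variants, is_germline = is_germ)
}

# does the subtree rooted at `node` contain an SNV or an LOH event?
subtree_has_support <- function(tree, data, node) {
  sub <- tree_subtree(tree, node)
  for (nd in sub)
    for (e in tree$events[[nd]])
      if (e$kind == "SNV") return(TRUE)
  rec <- cna_event_records(tree, data)
  any(rec$loh & rec$node %in% sub)
}

#' Simulate a ground-truth event tree
#'
#' Topology is uniform over labelled rooted trees (Pruefer decoding);
#' somatic SNVs are spread so that every non-root node carries at least
#' one; germline SNPs sit at the root; CNAs are placed respecting the
#' one-per-region-per-lineage and allele-availability constraints, with a
#' configurable fraction required to be supported by an SNV or LOH at or
#' below their node.
#'
#' @param config a [sim_config].
#' @param meta optional metadata from a previous call (internal).
#' @return A list with `tree` (an [event_tree]) and `data_template` (a
#'   skeleton [panel_data] carrying the metadata; counts all zero).
#' @export
simulate_tree <- function(config = sim_config(), meta = NULL) {
  meta <- meta %||% sim_metadata(config)
  nv <- nrow(meta$variants)
  # a metadata-only panel_data used for genotype bookkeeping
  dummy <- matrix(1L, 1L, config$n_regions,
                  dimnames = list("cell_0", meta$regions$id))
  zerov <- matrix(0L, 1L, nv, dimnames = list("cell_0", meta$variants$id))
  template <- panel_data(dummy, zerov, zerov, meta$variants, meta$regions)

  n <- config$n_nodes
  n_support <- round(config$snv_support_fraction * config$n_cnas)
  n_unsup <- config$n_cnas - n_support

  for (topo_try in seq_len(200L)) {
    seq <- if (n > 2L) sample.int(n, n - 2L, replace = TRUE) else integer(0)
    parent <- prufer_to_parent(seq, n)
    # SNV-unsupported CNAs need leaves whose subtree carries no SNV
    leaves <- setdiff(seq_len(n), parent[!is.na(parent)])
    leaves <- setdiff(leaves, 1L)
    if (length(leaves) >= n_unsup) break
  }
  reserved <- if (n_unsup > 0L) sample(leaves, n_unsup) else integer(0)
  snv_nodes <- setdiff(seq_len(n)[-1L], reserved)
  somatic <- which(!meta$is_germline)
  if (length(somatic) < length(snv_nodes))
    stop("need at least ", length(snv_nodes), " somatic SNVs for this tree",
         call. = FALSE)

  events <- rep(list(list()), n)
  for (i in which(meta$is_germline))
    events[[1L]][[length(events[[1L]]) + 1L]] <- new_event("SNV", i)
  if (length(snv_nodes) > 0L) {
    first <- if (length(somatic) == 1L) somatic else
      sample(somatic, length(snv_nodes))
    rest <- setdiff(somatic, first)
    target <- c(snv_nodes,
                if (length(rest) > 0L)
                  sample(snv_nodes, length(rest), replace = TRUE))
    for (r in seq_along(c(first, rest))) {
      v <- c(first, rest)[r]
      events[[target[r]]][[length(events[[target[r]]]) + 1L]] <-
        new_event("SNV", v)
    }
  } else if (length(somatic) > 0L) {
    stop("no non-root nodes available for somatic SNVs", call. = FALSE)
  }
  tree <- event_tree(parent, events)

  placed_sup <- 0L
  placed_unsup <- 0L
  for (attempt in seq_len(5000L)) {
    if (placed_sup + placed_unsup >= config$n_cnas) break
    want_support <- placed_sup < n_support
    if (n == 1L) break # single-node simulations carry no somatic CNAs
    # CNAs are somatic: never at the root (the non-neoplastic population),
    # where they would be confounded with the amplification weights
    kind <- if (want_support) draw1(c("GAIN", "LOSS", "CNLOH")) else
      draw1(c("GAIN", "LOSS"))
    node <- if (want_support) draw1(setdiff(seq_len(n)[-1L], reserved)) else
      draw1(reserved)
    k <- draw1(which(meta$regions$usable_for_cna))
    cand <- tree
    alle <- draw_alleles(kind, k, node, cand, template)
    if (is.null(alle)) next
    if (kind == "CNLOH" && length(alle) == 0L) next
    if (length(alle) == 0L) alle <- NULL
    cand$events[[node]][[length(cand$events[[node]]) + 1L]] <-
      new_event(kind, k, alle)
    if (length(validate_tree(cand, template)) > 0L) next
    sup <- subtree_has_support(cand, template, node)
    if (want_support != sup) next
    tree <- cand
    if (want_support) placed_sup <- placed_sup + 1L
    else placed_unsup <- placed_unsup + 1L
  }
  if (placed_sup + placed_unsup < config$n_cnas)
    stop("could not place ", config$n_cnas, " CNAs on this tree; ",
         "try different dimensions", call. = FALSE)
  list(tree = tree, data_template = template, meta = meta)
}

# beta-binomial draw
rbetabinom <- function(n, size, f, omega) {
  p <- rbeta(n, omega * f, omega * (1 - f))
  rbinom(n, size, p)
}

#' Simulate read counts for a ground-truth tree
#'
#' Follows the generative model: node weights are Dirichlet, cells attach
#' to nodes (or node pairs for doublets), per-cell total depths are
#' log-normal, region depths are negative binomial around the
#' copy-number- and efficiency-scaled expectation, locus depths are the
#' multinomial share of one amplicon, and ALT counts come from the
#' allele-specific dropout + sequencing-error beta-binomial mechanism
#' (conditioned on at least one copy amplifying).
#'
#' @param sim result of [simulate_tree()].
#' @param config the same [sim_config].
#' @param params a [model_params] supplying `omega_hom`/`omega_het`.
#' @param pi,mu,rho optional fixed node weights, dropout rates and region
#'   weights overriding the random draws (used for parametric bootstrap).
#' @return A list with `data` (a [panel_data]) and `truth` (tree, node
#'   weights, per-cell attachments and doublet flags, true dropout and
#'   region weights, per-cell amplified-copy counts).
#' @export
simulate_cells <- function(sim, config = sim_config(),
                           params = model_params(), pi = NULL, mu = NULL,
                           rho = NULL) {
  tree <- sim$tree
  meta <- sim$meta
  template <- sim$data_template
  n <- n_nodes(tree)
  nr <- config$n_regions
  nv <- nrow(meta$variants)
  nc <- config$n_cells

  if (is.null(pi)) {
    pi <- as.numeric(rgamma(n, config$concentration))
    if (sum(pi) == 0) pi <- rep(1, n)
    pi <- pi / sum(pi)
  }
  if (is.null(rho)) {
    rho <- meta$regions$n_amplicons
    if (config$coverage_mode == "nonuniform")
      rho <- rho * rlnorm(nr, 0, config$coverage_sigma)
    rho <- rho / sum(rho)
  }
  if (is.null(mu))
    mu <- pmin(pmax(rnorm(nv, config$dropout_mean, config$dropout_sd),
                    0.005), 0.45)

  is_doublet <- runif(nc) < config$doublet_rate
  node1 <- sample.int(n, nc, replace = TRUE, prob = pi)
  node2 <- ifelse(is_doublet,
                  sample.int(n, nc, replace = TRUE, prob = pi), NA_integer_)

  g <- genotypes_all(tree, template)
  cn <- g$region_cn[node1, , drop = FALSE]
  cr <- g$cr[node1, , drop = FALSE]
  ca <- g$ca[node1, , drop = FALSE]
  if (any(is_doublet)) {
    d2 <- which(is_doublet)
    cn[d2, ] <- (cn[d2, , drop = FALSE] +
                   g$region_cn[node2[d2], , drop = FALSE]) / 2
    cr[d2, ] <- cr[d2, , drop = FALSE] + g$cr[node2[d2], , drop = FALSE]
    ca[d2, ] <- ca[d2, , drop = FALSE] + g$ca[node2[d2], , drop = FALSE]
  }

  total_depth <- pmax(rlnorm(nc, log(config$depth_mean *
                                       sum(meta$regions$n_amplicons)),
                             0.25), 1)

  tilt <- matrix(1, nc, nr)
  tilted_regions <- integer(0)
  if (config$coverage_correlation == "on") {
    tilted_regions <- sample.int(nr, nr %/% 2)
    z <- runif(nc) < 0.5
    tilt[z, tilted_regions] <- 1 + config$correlation_gamma
  }

  w <- cn * rep(rho, each = nc) * tilt
  m <- total_depth * w / rowSums(w)
  region_depth <- matrix(rnbinom_mat(m, config$theta), nc, nr)

  # locus depths: multinomial split of the region's reads over its
  # equally-weighted amplicons; each variant occupies its own amplicon
  var_depth <- matrix(0L, nc, nv)
  for (k in seq_len(nr)) {
    vars_k <- which(meta$variants$region == k)
    if (length(vars_k) == 0L) next
    remaining <- region_depth[, k]
    amp_left <- meta$regions$n_amplicons[k]
    for (i in vars_k) {
      var_depth[, i] <- rbinom(nc, remaining, 1 / amp_left)
      remaining <- remaining - var_depth[, i]
      amp_left <- amp_left - 1L
    }
  }

  alt <- matrix(0L, nc, nv)
  amp_r <- matrix(0L, nc, nv) # amplified REF copies (ground truth)
  amp_a <- matrix(0L, nc, nv)
  for (i in seq_len(nv)) {
    cri <- cr[, i]; cai <- ca[, i]
    ktot <- integer(nc); ltot <- integer(nc)
    todo <- which(cri + cai > 0)
    while (length(todo) > 0L) { # redraw total-dropout cells
      ktot[todo] <- rbinom(length(todo), cri[todo], 1 - mu[i])
      ltot[todo] <- rbinom(length(todo), cai[todo], 1 - mu[i])
      todo <- todo[ktot[todo] + ltot[todo] == 0L]
    }
    amp_r[, i] <- ktot; amp_a[, i] <- ltot
    f <- ifelse(ktot + ltot > 0,
                (ltot * (1 - config$eps) + ktot * config$eps) /
                  pmax(ktot + ltot, 1L),
                config$eps) # deleted locus: error reads only
    omega <- ifelse(ktot == 0L | ltot == 0L, params$omega_hom,
                    params$omega_het)
    alt[, i] <- rbetabinom(nc, var_depth[, i], pmin(pmax(f, 1e-9), 1 - 1e-9),
                           omega)
  }

  cell_ids <- paste0("cell_", seq_len(nc))
  dimnames(region_depth) <- list(cell_ids, meta$regions$id)
  dimnames(alt) <- dimnames(var_depth) <- list(cell_ids, meta$variants$id)
  keep <- rowSums(region_depth) > 0
  data <- panel_data(region_depth[keep, , drop = FALSE],
                     alt[keep, , drop = FALSE],
                     var_depth[keep, , drop = FALSE],
                     meta$variants, meta$regions)
  truth <- list(tree = tree, node_weights = pi,
                attachment = node1[keep], attachment2 = node2[keep],
                is_doublet = is_doublet[keep], dropout_rates = mu,
                region_weights = rho, latent_total = total_depth[keep],
                tilted_regions = tilted_regions,
                amplified_ref = amp_r[keep, , drop = FALSE],
                amplified_alt = amp_a[keep, , drop = FALSE],
                genotype_cr = cr[keep, , drop = FALSE],
                genotype_ca = ca[keep, , drop = FALSE])
  list(data = data, truth = truth)
}

# elementwise NB draws around a mean matrix
rnbinom_mat <- function(m, theta) {
  out <- stats::rnbinom(length(m), size = theta, mu = as.numeric(m))
  as.integer(out)
}

#' One-call simulation of a synthetic dataset
#'
#' @param config a [sim_config].
#' @param params a [model_params].
#' @param seed optional seed set before generation.
#' @return As [simulate_cells()], plus the `tree`.
#' @export
simulate_dataset <- function(config = sim_config(),
                             params = model_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sim <- simulate_tree(config)
  out <- simulate_cells(sim, config, params)
  out$tree <- sim$tree
  out
}
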