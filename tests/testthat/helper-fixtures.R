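# deterministic toy panel: counts drawn once under a fixed seed
toy_panel <- function(n_cells = 4, n_regions = 3, n_variants = 2, seed = 1,
                      var_region = NULL, pop_freq = NULL, depth = 30) {
  set.seed(seed)
  rd <- matrix(rpois(n_cells * n_regions, depth), n_cells, n_regions,
               dimnames = list(paste0("c", seq_len(n_cells)),
                               paste0("R", seq_len(n_regions))))
  if (is.null(var_region))
    var_region <- rep_len(seq_len(n_regions), n_variants)
  dp <- matrix(rpois(n_cells * n_variants, depth / 2), n_cells, n_variants)
  a <- matrix(rbinom(length(dp), dp, 0.4), n_cells, n_variants)
  if (is.null(pop_freq)) pop_freq <- rep(NA_real_, n_variants)
  variants <- data.frame(id = paste0("v", seq_len(n_variants)),
                         region = var_region,
                         chrom = paste0("chr", var_region), pos = seq_len(n_variants) * 100,
                         pop_freq = pop_freq)
  regions <- data.frame(id = paste0("R", seq_len(n_regions)),
                        chrom = paste0("chr", seq_len(n_regions)),
                        order_index = 1L, n_amplicons = 1L,
                        usable_for_cna = TRUE)
  panel_data(rd, a, dp, variants, regions)
}

# panel whose regions share chromosomes (for contiguity-merging tests)
toy_panel_chrom <- function(n_cells = 3, orders = c(1, 2, 3, 5, 1),
                            chroms = c("chr7", "chr7", "chr7", "chr7", "chr9"),
                            n_variants = 2, var_region = c(1, 5), seed = 2) {
  set.seed(seed)
  nr <- length(orders)
  rd <- matrix(rpois(n_cells * nr, 25), n_cells, nr,
               dimnames = list(paste0("c", seq_len(n_cells)),
                               paste0("R", seq_len(nr))))
  dp <- matrix(rpois(n_cells * n_variants, 15), n_cells, n_variants)
  a <- matrix(rbinom(length(dp), dp, 0.4), n_cells, n_variants)
  variants <- data.frame(id = paste0("v", seq_len(n_variants)),
                         region = var_region, chrom = chroms[var_region],
                         pos = seq_len(n_variants) * 100,
                         pop_freq = NA_real_)
  regions <- data.frame(id = paste0("R", seq_len(nr)), chrom = chroms,
                        order_index = orders, n_amplicons = 1L,
                        usable_for_cna = TRUE)
  panel_data(rd, a, dp, variants, regions)
}

ev_snv <- function(i) list(kind = "SNV", target = as.integer(i),
                           alleles = NULL)
ev_cna <- function(kind, k, alleles = NULL)
  list(kind = kind, target = as.integer(k), alleles = alleles)

# per-cell per-attachment log-likelihood from the exported scalar ops;
# independent oracle for the compiled path
scalar_cell_ll <- function(geno, cell, data, params, rho, mu) {
  nr <- nrow(data$regions)
  ll <- 0
  for (k in seq_len(nr))
    ll <- ll + region_depth_loglik(data$region_depth[cell, k],
                                   data$cell_total[cell], geno$region_cn, k,
                                   rho, params$theta)
  for (i in seq_len(nrow(data$variants))) {
    d <- data$var_depth[cell, i]
    a <- data$alt_counts[cell, i]
    if (geno$cr[i] + geno$ca[i] == 0) {
      if (d > 0)
        ll <- ll + beta_binomial_loglik(a, d, params$eps, params$omega_hom)
    } else {
      ll <- ll + allelic_loglik(a, d, geno$cr[i], geno$ca[i], mu[i], params)
    }
  }
  ll
}

# brute-force attachment-marginalised likelihood (Eq-style double sum over
# ordered node pairs), in probability space via logsumexp
brute_force_tree_loglik <- function(tree, data, params, pi, rho, mu) {
  n <- length(pi)
  genos <- lapply(seq_len(n), function(nd) node_genotype(tree, nd, data))
  delta <- params$doublet_rate
  total <- 0
  for (j in seq_along(data$cell_ids)) {
    terms <- numeric(0)
    for (nd in seq_len(n)) {
      if (pi[nd] == 0) next
      terms <- c(terms, log1p(-delta) + log(pi[nd]) +
                   scalar_cell_ll(genos[[nd]], j, data, params, rho, mu))
    }
    if (delta > 0) {
      for (n1 in seq_len(n)) for (n2 in seq_len(n)) {
        if (pi[n1] == 0 || pi[n2] == 0) next
        g <- doublet_genotype(genos[[n1]], genos[[n2]])
        terms <- c(terms, log(delta) + log(pi[n1]) + log(pi[n2]) +
                     scalar_cell_ll(g, j, data, params, rho, mu))
      }
    }
    m <- max(terms)
    total <- total + m + log(sum(exp(terms - m)))
  }
  total
}

# independent lineage-constraint checker: enumerate all root-to-leaf paths
brute_force_lineage_ok <- function(tree, data) {
  n <- length(tree$parent)
  leaves <- setdiff(seq_len(n), tree$parent[!is.na(tree$parent)])
  for (leaf in leaves) {
    path <- leaf
    while (!is.na(tree$parent[path[1L]])) path <- c(tree$parent[path[1L]], path)
    regs <- unlist(lapply(path, function(nd)
      vapply(tree$events[[nd]],
             function(e) if (e$kind != "SNV") e$target else NA_integer_, 0L)))
    regs <- regs[!is.na(regs)]
    if (anyDuplicated(regs)) return(FALSE)
  }
  TRUE
}
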