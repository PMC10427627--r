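#' Search configuration for tree inference
#'
#' @param n_chains independent annealing chains per phase; the best final
#'   posterior wins.
#' @param iterations length-2 vector: iterations for the CNA-free phase and
#'   the CNA phase.
#' @param t_init,t_final temperature schedule endpoints (geometric decay).
#' @param seed integer seed governing all randomness of the run.
#' @param doublets_enabled model doublet attachments during inference.
#' @param candidate_depth_ratio_threshold a region becomes a CNA candidate
#'   when its responsibility-weighted normalised depth at some non-root
#'   node departs from the root's by more than this relative threshold.
#' @param min_node_weight nodes lighter than this fraction of cells are
#'   ignored when screening for candidate regions.
#' @param min_region_depth_fraction regions with estimated weight below
#'   this are excluded from CNA inference (poorly amplified regions give
#'   unreliable depth signal).
#' @param min_region_amplicons regions with fewer amplicons are excluded
#'   from CNA inference.
#' @param penalties a [prior_penalties] object.
#' @param em_iter_search,em_tol_search inner EM budget during annealing.
#' @param em_iter_final,em_tol_final EM budget for the final refit.
#' @param max_nodes hard cap on tree size during search.
#' @return A list of class `infer_config`.
#' @export
infer_config <- function(n_chains = 2, iterations = c(1500, 1500),
                         t_init = 8, t_final = 1, seed = 1,
                         doublets_enabled = FALSE,
                         candidate_depth_ratio_threshold = 0.2,
                         min_node_weight = 0.01,
                         min_region_depth_fraction = 0.002,
                         min_region_amplicons = 1,
                         penalties = prior_penalties(),
                         em_iter_search = 10, em_tol_search = 0.1,
                         em_iter_final = 200, em_tol_final = 1e-4,
                         max_nodes = 16) {
  stopifnot(t_init >= t_final, t_final > 0, all(iterations > 0),
            n_chains >= 1)
  structure(as.list(environment()), class = "infer_config")
}

# decode a Pruefer sequence (values in 1..n) into a parent vector rooted at 1
prufer_to_parent <- function(seq, n) {
  if (n == 1L) return(NA_integer_)
  if (n == 2L) return(c(NA_integer_, 1L))
  stopifnot(length(seq) == n - 2L, all(seq >= 1L), all(seq <= n))
  degree <- rep(1L, n)
  for (s in seq) degree[s] <- degree[s] + 1L
  edges <- matrix(0L, n - 1L, 2L)
  for (r in seq_along(seq)) {
    l <- which(degree == 1L)[1L]
    edges[r, ] <- c(l, seq[r])
    degree[l] <- 0L
    degree[seq[r]] <- degree[seq[r]] - 1L
  }
  edges[n - 1L, ] <- which(degree == 1L)
  # orient away from node 1 by BFS
  adj <- vector("list", n)
  for (r in seq_len(n - 1L)) {
    adj[[edges[r, 1L]]] <- c(adj[[edges[r, 1L]]], edges[r, 2L])
    adj[[edges[r, 2L]]] <- c(adj[[edges[r, 2L]]], edges[r, 1L])
  }
  parent <- rep(NA_integer_, n)
  visited <- rep(FALSE, n)
  frontier <- 1L; visited[1L] <- TRUE
  while (length(frontier) > 0L) {
    nxt <- integer(0)
    for (u in frontier) for (v in adj[[u]]) if (!visited[v]) {
      parent[v] <- u; visited[v] <- TRUE; nxt <- c(nxt, v)
    }
    frontier <- nxt
  }
  parent
}

#' Random initial tree for the annealing search
#'
#' The node count is drawn uniformly from 3 to 10 (capped at one node per
#' variant plus the root), the topology is a uniform random labelled tree
#' obtained by decoding a random Pruefer sequence and rooting it at node 1,
#' and the variants are assigned to nodes uniformly at random.  The
#' initial tree carries no CNA events.
#'
#' @param data a [panel_data] object.
#' @return A valid CNA-free [event_tree].
#' @export
initial_tree <- function(data) {
  nv <- nrow(data$variants)
  stopifnot(nv >= 1)
  n <- sample(3:10, 1L)
  n <- min(n, nv + 1L)
  n <- max(n, 2L)
  seq <- if (n > 2L) sample.int(n, n - 2L, replace = TRUE) else integer(0)
  parent <- prufer_to_parent(seq, n)
  events <- rep(list(list()), n)
  for (i in seq_len(nv)) {
    nd <- sample.int(n, 1L)
    events[[nd]][[length(events[[nd]]) + 1L]] <- new_event("SNV", i)
  }
  event_tree(parent, events)
}

# ---- proposal moves --------------------------------------------------------

# uniform draw helper that works for length-1 vectors
draw1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

remove_node_event <- function(tree, node, idx) {
  tree$events[[node]] <- tree$events[[node]][-idx]
  tree
}

# available alleles for a CNA of `kind` on region k at `node`, given the
# pre-event genotype there; returns NULL if infeasible, else a candidate
# named allele vector drawn uniformly among available choices
draw_alleles <- function(kind, k, node, tree, data) {
  g <- genotypes_all(tree, data)
  vars_k <- which(data$variants$region == k)
  if (length(vars_k) == 0L) return(character(0))
  alle <- character(0)
  for (i in vars_k) {
    avail <- c(if (g$cr[node, i] >= 1) "ref", if (g$ca[node, i] >= 1) "alt")
    if (length(avail) == 0L) return(NULL)
    alle[as.character(i)] <- draw1(avail)
  }
  alle
}

move_prune_reattach <- function(tree, data) {
  n <- n_nodes(tree)
  if (n < 3L) return(NULL)
  u <- draw1(2:n)
  sub <- tree_subtree(tree, u)
  valid <- setdiff(seq_len(n), c(sub, tree$parent[u]))
  if (length(valid) == 0L) return(NULL)
  tree$parent[u] <- draw1(valid)
  list(tree = tree, log_ratio = 0) # |valid| is invariant under the move
}

move_swap_events <- function(tree, data) {
  n <- n_nodes(tree)
  if (n < 2L) return(NULL)
  uv <- sample.int(n, 2L)
  tmp <- tree$events[[uv[1L]]]
  tree$events[[uv[1L]]] <- tree$events[[uv[2L]]]
  tree$events[[uv[2L]]] <- tmp
  list(tree = tree, log_ratio = 0)
}

move_snv <- function(tree, data) {
  n <- n_nodes(tree)
  if (n < 2L) return(NULL)
  snvs <- snv_placements(tree)
  if (nrow(snvs) == 0L) return(NULL)
  r <- draw1(seq_len(nrow(snvs)))
  from <- snvs$node[r]; v <- snvs$variant[r]
  to <- draw1(setdiff(seq_len(n), from))
  idx <- which(vapply(tree$events[[from]], function(e)
    e$kind == "SNV" && e$target == v, TRUE))[1L]
  tree <- remove_node_event(tree, from, idx)
  tree$events[[to]][[length(tree$events[[to]]) + 1L]] <- new_event("SNV", v)
  list(tree = tree, log_ratio = 0)
}

move_split_merge <- function(tree, data, max_nodes) {
  n <- n_nodes(tree)
  do_split <- if (n == 1L) TRUE else if (n >= max_nodes) FALSE
  else runif(1) < 0.5
  if (do_split) {
    u <- draw1(seq_len(n))
    e_u <- length(tree$events[[u]])
    ch_u <- which(tree$parent == u)
    w <- n + 1L
    take_e <- if (e_u > 0L) which(runif(e_u) < 0.5) else integer(0)
    take_c <- if (length(ch_u) > 0L) ch_u[runif(length(ch_u)) < 0.5] else integer(0)
    tree$parent <- c(tree$parent, u)
    tree$events[[w]] <- tree$events[[u]][take_e]
    tree$events[[u]] <- tree$events[[u]][setdiff(seq_len(e_u), take_e)]
    if (length(take_c) > 0L) tree$parent[take_c] <- w
    fwd <- log(0.5) - log(n) + (e_u + length(ch_u)) * log(0.5)
    rev <- log(0.5) - log(n) # merge picks one of n non-root nodes of tree'
    pi_transfer <- function(pi) { p <- c(pi, pi[u] / 2); p[u] <- pi[u] / 2; p }
    list(tree = tree, log_ratio = rev - fwd, pi_transfer = pi_transfer)
  } else {
    if (n < 2L) return(NULL)
    w <- draw1(2:n)
    u <- tree$parent[w]
    e_u_new <- length(tree$events[[u]]) + length(tree$events[[w]])
    ch <- which(tree$parent == w)
    ch_u_new <- length(which(tree$parent == u)) - 1L + length(ch)
    tree$events[[u]] <- c(tree$events[[u]], tree$events[[w]])
    if (length(ch) > 0L) tree$parent[ch] <- u
    # drop node w, relabelling the last node into its slot
    keep <- setdiff(seq_len(n), w)
    relab <- integer(n); relab[keep] <- seq_len(n - 1L)
    parent <- tree$parent[keep]
    parent[!is.na(parent)] <- relab[parent[!is.na(parent)]]
    tree <- event_tree(parent, tree$events[keep])
    fwd <- log(0.5) - log(n - 1L)
    rev <- log(0.5) - log(n - 1L) + (e_u_new + ch_u_new) * log(0.5)
    pi_transfer <- function(pi) { p <- pi; p[u] <- p[u] + p[w]; p[keep] }
    list(tree = tree, log_ratio = rev - fwd, pi_transfer = pi_transfer)
  }
}

move_add_remove_cna <- function(tree, data, candidates, cnloh_regions,
                                allow_add) {
  cnas <- cna_placements(tree)
  n <- n_nodes(tree)
  # CNAs are proposed on non-root nodes only: a root CNA is confounded
  # with the region weights estimated from root-attached cells.  Gains and
  # losses are restricted to the depth-screened candidates; CNLOH is
  # copy-neutral (no depth footprint) and may target any usable
  # variant-bearing region.
  region_set <- function(kind)
    if (kind == "CNLOH") cnloh_regions else candidates
  can_add <- allow_add && n >= 2L &&
    (length(candidates) > 0L || length(cnloh_regions) > 0L)
  can_del <- nrow(cnas) > 0L
  if (!can_add && !can_del) return(NULL)
  p_add <- if (can_add && can_del) 0.5 else if (can_add) 1 else 0
  if (runif(1) < p_add) {
    kind <- draw1(c("GAIN", "LOSS", "CNLOH"))
    rs <- region_set(kind)
    if (length(rs) == 0L) return(NULL)
    k <- draw1(rs)
    node <- draw1(seq_len(n)[-1L])
    alle <- draw_alleles(kind, k, node, tree, data)
    if (is.null(alle)) return(NULL)
    if (kind == "CNLOH" && length(alle) == 0L) return(NULL) # vacuous
    if (length(alle) == 0L) alle <- NULL
    nvk <- length(which(data$variants$region == k))
    tree$events[[node]][[length(tree$events[[node]]) + 1L]] <-
      new_event(kind, k, alle)
    fwd <- log(p_add) - log(3) - log(length(rs)) - log(n - 1L) -
      nvk * log(2)
    rev <- log(0.5) - log(nrow(cnas) + 1L) # delete is available after an add
    list(tree = tree, log_ratio = rev - fwd)
  } else {
    r <- draw1(seq_len(nrow(cnas)))
    node <- cnas$node[r]; k <- cnas$region[r]
    rs <- region_set(cnas$kind[r])
    nvk <- length(which(data$variants$region == k))
    tree <- remove_node_event(tree, node, cnas$event_index[r])
    p_del <- if (can_add) 0.5 else 1
    fwd <- log(p_del) - log(nrow(cnas))
    n_after <- nrow(cnas) - 1L
    p_add_rev <- if (n_after > 0L && can_add) 0.5 else 1
    rev <- if (can_add && length(rs) > 0L)
      log(p_add_rev) - log(3) - log(length(rs)) -
        log(n - 1L) - nvk * log(2)
    else -Inf # unreachable configuration; SA never needs the exact value
    list(tree = tree, log_ratio = rev - fwd)
  }
}

move_toggle_allele <- function(tree, data) {
  cnas <- cna_placements(tree)
  if (nrow(cnas) == 0L) return(NULL)
  withv <- which(vapply(seq_len(nrow(cnas)), function(r) {
    e <- tree$events[[cnas$node[r]]][[cnas$event_index[r]]]
    !is.null(e$alleles) && length(e$alleles) > 0L
  }, TRUE))
  if (length(withv) == 0L) return(NULL)
  r <- draw1(withv)
  e <- tree$events[[cnas$node[r]]][[cnas$event_index[r]]]
  j <- draw1(seq_along(e$alleles))
  e$alleles[j] <- if (e$alleles[j] == "ref") "alt" else "ref"
  tree$events[[cnas$node[r]]][[cnas$event_index[r]]] <- e
  list(tree = tree, log_ratio = 0)
}

#' Propose a neighbouring tree for the annealing search
#'
#' Draws one of six move types (prune-and-reattach, swap node event sets,
#' move an SNV, split/merge a node, add/remove a CNA, toggle a CNA's
#' allele), applies it, and returns the new tree together with the
#' log Hastings ratio of the move pair.  Draws that violate the tree
#' constraints are resampled up to a bound, after which the move type is
#' redrawn; CNA additions are restricted to `candidate_regions`.
#'
#' CNAs with a depth footprint (gains and losses) may only be added to
#' `candidate_regions`; CNLOH events, which are copy-neutral and leave no
#' depth signal, may be added to any usable variant-bearing region, since
#' their evidence comes from allelic imbalance instead.
#'
#' @param tree current [event_tree].
#' @param data a [panel_data] object.
#' @param candidate_regions integer region indices gains/losses may be
#'   added to.
#' @param allow_cnas enable CNA moves (phase 2).
#' @param max_nodes cap on node count.
#' @param max_tries validity resampling bound per move type.
#' @return A list with `tree`, `log_ratio` and `move` (the move name), or
#'   the unchanged tree with `move = "none"` if no valid move was found.
#' @export
propose <- function(tree, data, candidate_regions = integer(0),
                    allow_cnas = FALSE, max_nodes = 16, max_tries = 20,
                    cnloh_regions = NULL) {
  if (is.null(cnloh_regions))
    cnloh_regions <- which(data$regions$usable_for_cna &
                             tabulate(data$variants$region,
                                      nbins = nrow(data$regions)) > 0L)
  # in the CNA phase the SNV structure is largely settled, so CNA moves
  # get a larger share of proposals
  moves <- if (allow_cnas)
    c(prune = 0.17, swap = 0.07, snv = 0.17, splitmerge = 0.14,
      cna = 0.38, toggle = 0.07)
  else c(prune = 0.25, swap = 0.1, snv = 0.25, splitmerge = 0.2,
         cna = 0.15, toggle = 0.05)
  has_cna <- nrow(cna_placements(tree)) > 0L
  if (!allow_cnas || (length(candidate_regions) == 0L &&
                        length(cnloh_regions) == 0L && !has_cna))
    moves["cna"] <- 0
  if (!has_cna) moves["toggle"] <- 0
  moves <- moves / sum(moves)

  for (outer in seq_len(8L)) {
    mv <- sample(names(moves), 1L, prob = moves)
    for (try in seq_len(max_tries)) {
      res <- switch(mv,
        prune = move_prune_reattach(tree, data),
        swap = move_swap_events(tree, data),
        snv = move_snv(tree, data),
        splitmerge = move_split_merge(tree, data, max_nodes),
        cna = move_add_remove_cna(tree, data, candidate_regions,
                                  cnloh_regions, allow_add = allow_cnas),
        toggle = move_toggle_allele(tree, data))
      if (is.null(res)) break
      # besides the model constraints, keep CNAs off the root (see above)
      root_cna <- any(vapply(res$tree$events[[1L]],
                             function(e) e$kind != "SNV", TRUE))
      if (!root_cna && length(validate_tree(res$tree, data)) == 0L) {
        res$move <- mv
        return(res)
      }
    }
  }
  list(tree = tree, log_ratio = 0, move = "none")
}

# remove event-free non-root nodes: their genotype equals their parent's,
# so reattaching their children and transferring their weight leaves the
# likelihood unchanged while strictly improving the prior
prune_empty_nodes <- function(tree, pi = NULL) {
  repeat {
    empty <- which(vapply(tree$events, length, 0L) == 0L)
    empty <- setdiff(empty, 1L)
    if (length(empty) == 0L) break
    w <- empty[1L]
    u <- tree$parent[w]
    ch <- which(tree$parent == w)
    if (length(ch) > 0L) tree$parent[ch] <- u
    keep <- setdiff(seq_len(n_nodes(tree)), w)
    relab <- integer(n_nodes(tree)); relab[keep] <- seq_along(keep)
    parent <- tree$parent[keep]
    parent[!is.na(parent)] <- relab[parent[!is.na(parent)]]
    if (!is.null(pi)) {
      pi[u] <- pi[u] + pi[w]
      pi <- pi[keep]
    }
    tree <- event_tree(parent, tree$events[keep])
  }
  list(tree = tree, pi = pi)
}

# ---- annealing -------------------------------------------------------------

# lexicographic preference among (near-)equal-posterior trees: fewer nodes,
# then fewer CNA events, then lexicographically smaller event placement
tree_signature <- function(tree) {
  paste(vapply(seq_len(n_nodes(tree)), function(nd) {
    evts <- vapply(tree$events[[nd]], function(e)
      paste0(e$kind, e$target), "")
    paste0(nd, ":", paste(sort(evts), collapse = ","))
  }, ""), collapse = ";")
}

better_tree <- function(lp_new, tree_new, lp_old, tree_old, tol = 1e-9) {
  if (lp_new > lp_old + tol) return(TRUE)
  if (lp_new < lp_old - tol) return(FALSE)
  nn <- n_nodes(tree_new); no <- n_nodes(tree_old)
  if (nn != no) return(nn < no)
  cn <- nrow(cna_placements(tree_new)); co <- nrow(cna_placements(tree_old))
  if (cn != co) return(cn < co)
  tree_signature(tree_new) < tree_signature(tree_old)
}

#' Simulated-annealing search over event trees
#'
#' Runs a Metropolis chain with geometrically decaying temperature: at each
#' step a neighbouring tree is proposed, node weights and dropout rates are
#' refitted by a short warm-started EM, and the move is accepted with
#' probability `min(1, exp((logpost' - logpost)/T + log Hastings ratio))`
#' where the log posterior is the marginal log-likelihood plus the tree
#' log-prior and the dropout-rate log-prior.  The best state ever visited
#' is returned.
#'
#' @param data a [panel_data] object.
#' @param config an [infer_config].
#' @param params a [model_params].
#' @param allow_cnas enable CNA moves.
#' @param candidate_regions region indices CNAs may be added to.
#' @param rho region weights (`NULL`: uniform per amplicon).
#' @param init optional initial [event_tree] (`NULL`: random).
#' @param iterations chain length (defaults per phase from `config`).
#' @return A list with `tree`, `em` (an `em_fit`), `log_post` and
#'   `diagnostics` (acceptance rate, log-posterior trace).
#' @export
anneal <- function(data, config, params, allow_cnas = FALSE,
                   candidate_regions = integer(0), rho = NULL, init = NULL,
                   iterations = config$iterations[if (allow_cnas) 2 else 1]) {
  rho <- rho %||% default_region_weights(data, params)
  tree <- init %||% initial_tree(data)
  mu0 <- dropout_vector(data, params)
  cache <- make_ll_cache(data, params)
  em <- fit_em(tree, data, params, max_iter = config$em_iter_search,
               tol = config$em_tol_search, rho = rho, mu0 = mu0,
               cache = cache)
  lp <- em$log_post_trace[em$n_iter] +
    tree_log_prior(tree, data, config$penalties)
  best <- list(tree = tree, em = em, log_post = lp)
  lp_init <- lp
  n_accept <- 0L
  trace <- numeric(iterations)
  temps <- config$t_init *
    (config$t_final / config$t_init)^((seq_len(iterations) - 1) /
                                        max(iterations - 1, 1))
  cnloh_regions <- which(data$regions$usable_for_cna &
                           tabulate(data$variants$region,
                                    nbins = nrow(data$regions)) > 0L)
  for (it in seq_len(iterations)) {
    prop <- propose(tree, data, candidate_regions, allow_cnas,
                    config$max_nodes, cnloh_regions = cnloh_regions)
    if (prop$move != "none") {
      pi0 <- if (!is.null(prop$pi_transfer)) prop$pi_transfer(em$pi)
        else if (n_nodes(prop$tree) == n_nodes(tree)) em$pi else NULL
      if (!is.null(pi0)) { # floor so the short EM can repopulate any node
        pi0 <- pmax(pi0, 1e-3)
        pi0 <- pi0 / sum(pi0)
      }
      em_new <- fit_em(prop$tree, data, params,
                       max_iter = config$em_iter_search,
                       tol = config$em_tol_search, rho = rho,
                       pi0 = pi0, mu0 = em$mu, cache = cache)
      lp_new <- em_new$log_post_trace[em_new$n_iter] +
        tree_log_prior(prop$tree, data, config$penalties)
      if (log(runif(1)) < (lp_new - lp) / temps[it] + prop$log_ratio) {
        tree <- prop$tree; em <- em_new; lp <- lp_new
        n_accept <- n_accept + 1L
        if (better_tree(lp, tree, best$log_post, best$tree)) {
          # confirm with a longer EM so short-EM noise cannot inflate the best
          pruned <- prune_empty_nodes(tree, em$pi)
          em_chk <- fit_em(pruned$tree, data, params, max_iter = 40,
                           tol = 1e-3, rho = rho, pi0 = pruned$pi,
                           mu0 = em$mu, cache = cache)
          lp_chk <- em_chk$log_post_trace[em_chk$n_iter] +
            tree_log_prior(pruned$tree, data, config$penalties)
          if (better_tree(lp_chk, pruned$tree, best$log_post, best$tree))
            best <- list(tree = pruned$tree, em = em_chk, log_post = lp_chk)
        }
      }
    }
    trace[it] <- lp
  }
  best$diagnostics <- list(acceptance_rate = n_accept / iterations,
                           init_log_post = lp_init,
                           log_post_trace = trace)
  best
}

# nodes whose root path carries only germline-candidate SNVs (and no CNA):
# these attach the non-neoplastic cell population
normal_nodes <- function(tree, data) {
  germline <- !is.na(data$variants$pop_freq)
  normal <- rep(FALSE, n_nodes(tree))
  normal[1L] <- TRUE
  for (nd in node_order(tree)[-1L]) {
    if (!normal[tree$parent[nd]]) next
    vars <- vapply(tree$events[[nd]],
                   function(e) if (e$kind == "SNV") e$target else NA_integer_,
                   0L)
    normal[nd] <- length(vars) == 0L ||
      (!anyNA(vars) && all(germline[vars]))
  }
  normal
}

#' Estimate region amplification weights from non-neoplastic cells
#'
#' In a CNA-free tree the cells attached to the root are the
#' non-neoplastic (diploid) population; their depth profile estimates the
#' probability `rho_k` of a read falling in each region.  Since an
#' imperfect phase-1 tree may leave a germline SNP just below the root,
#' every node whose root path carries only germline-candidate variants
#' (known population frequency) counts as normal.  When fewer than
#' `min_root_weight` of the cells sit at such nodes, all cells are used
#' (every genotype in a CNA-free tree is diploid in copy number).
#'
#' @param em an `em_fit` for a CNA-free tree.
#' @param tree the CNA-free [event_tree] the fit refers to.
#' @param data a [panel_data] object.
#' @param min_root_weight normal-cell responsibility floor (fraction of
#'   cells).
#' @return A simplex vector of region weights.
#' @export
estimate_region_weights <- function(em, tree, data, min_root_weight = 0.01) {
  n_cells <- length(data$cell_ids)
  if (n_cells == 0L) stop("no cells", call. = FALSE)
  normal <- normal_nodes(tree, data)
  w <- rowSums(em$responsibilities[, which(normal), drop = FALSE])
  if (sum(w) < min_root_weight * n_cells) w <- rep(1, n_cells)
  rho <- colSums(w * data$region_depth)
  rho / sum(rho)
}

#' Screen regions for potential copy-number alterations
#'
#' For every non-root node with weight at least `min_node_weight`, the
#' responsibility-weighted mean of the normalised depth
#' `D_kj / (D_j * rho_k)` is compared with the root's; a region whose
#' ratio departs by more than the threshold at some node is selected.
#' Regions with weight below `min_region_depth_fraction`, fewer than
#' `min_region_amplicons` amplicons, or flagged unusable are never
#' selected.
#'
#' @param em an `em_fit` for a CNA-free tree.
#' @param tree the CNA-free [event_tree] the fit refers to.
#' @param data a [panel_data] object.
#' @param rho region weights from [estimate_region_weights()].
#' @param config an [infer_config] (thresholds).
#' @return Integer vector of selected region indices.
#' @export
select_candidate_regions <- function(em, tree, data, rho,
                                     config = infer_config()) {
  t <- config$candidate_depth_ratio_threshold
  resp <- em$responsibilities
  n <- ncol(resp) - if (is.null(em$pairs)) 0L else nrow(em$pairs)
  norm_depth <- sweep(data$region_depth / data$cell_total, 2L, rho, `/`)
  node_w <- colSums(resp) / nrow(resp)
  node_mean <- function(nd) {
    w <- if (length(nd) == 1L) resp[, nd] else
      rowSums(resp[, nd, drop = FALSE])
    colSums(w * norm_depth) / sum(w)
  }
  # reference profile: the normal (root-path germline-only) population
  ref_nodes <- normal_nodes(tree, data)
  ref_w <- rowSums(resp[, which(ref_nodes), drop = FALSE])
  root_mean <- if (sum(ref_w) >= config$min_node_weight * nrow(resp))
    colSums(ref_w * norm_depth) / sum(ref_w) else colMeans(norm_depth)
  usable <- data$regions$usable_for_cna &
    rho >= config$min_region_depth_fraction &
    data$regions$n_amplicons >= config$min_region_amplicons
  selected <- rep(FALSE, nrow(data$regions))
  for (nd in seq_len(n)[-1L]) {
    if (node_w[nd] < config$min_node_weight) next
    ratio <- node_mean(nd) / root_mean
    selected <- selected | (ratio < 1 - t | ratio > 1 + t)
  }
  which(selected & usable)
}

#' Fit a clone tree to single-cell panel data
#'
#' The main fitting function.  Phase 1 anneals over CNA-free trees (the
#' region-depth factor is uninformative there, so only SNVs drive the
#' fit); the cells attached to the root of the phase-1 tree then calibrate
#' the region amplification weights, and regions whose normalised depth
#' deviates in some clone are short-listed as CNA candidates.  Phase 2
#' anneals over full event trees with CNA moves restricted to the
#' candidates, starting from the phase-1 tree.  A long EM refit of the
#' winning tree produces the final node weights, dropout rates and cell
#' attachment posteriors.
#'
#' @param data a [panel_data] object.
#' @param config an [infer_config].
#' @param params a [model_params]; `doublet_rate` is zeroed unless
#'   `config$doublets_enabled`.
#' @return An object of class `clone_tree_fit` with elements `tree`, `pi`,
#'   `mu`, `rho`, `log_post`, `responsibilities`, `pairs`,
#'   `candidate_regions`, `diagnostics`, `config`, `params`, `data`.
#' @export
fit_clone_tree <- function(data, config = infer_config(),
                           params = model_params()) {
  stopifnot(inherits(data, "panel_data"))
  set.seed(config$seed)
  if (!config$doublets_enabled) params$doublet_rate <- 0

  run_phase <- function(allow_cnas, candidates, rho, init) {
    chains <- lapply(seq_len(config$n_chains), function(ch)
      anneal(data, config, params, allow_cnas = allow_cnas,
             candidate_regions = candidates, rho = rho, init = init))
    best <- chains[[1L]]
    for (ch in chains[-1L])
      if (better_tree(ch$log_post, ch$tree, best$log_post, best$tree))
        best <- ch
    best$all_chains <- lapply(chains, function(x)
      list(log_post = x$log_post, diagnostics = x$diagnostics))
    best
  }

  phase1 <- run_phase(FALSE, integer(0), NULL, NULL)
  em1 <- fit_em(phase1$tree, data, params, max_iter = config$em_iter_final,
                tol = config$em_tol_final, mu0 = phase1$em$mu,
                pi0 = phase1$em$pi)
  rho <- estimate_region_weights(em1, phase1$tree, data)
  candidates <- select_candidate_regions(em1, phase1$tree, data, rho, config)

  phase2 <- run_phase(TRUE, candidates, rho, phase1$tree)
  em <- fit_em(phase2$tree, data, params, max_iter = config$em_iter_final,
               tol = config$em_tol_final, rho = rho, mu0 = phase2$em$mu,
               pi0 = phase2$em$pi)
  log_post <- em$log_post_trace[em$n_iter] +
    tree_log_prior(phase2$tree, data, config$penalties)

  structure(list(
    tree = phase2$tree, pi = em$pi, mu = em$mu, rho = rho,
    log_post = log_post, loglik = em$loglik,
    responsibilities = em$responsibilities, pairs = em$pairs,
    candidate_regions = candidates,
    diagnostics = list(phase1 = phase1$all_chains,
                       phase2 = phase2$all_chains,
                       phase1_tree = phase1$tree,
                       phase1_log_post = phase1$log_post,
                       phase2_log_post = phase2$log_post),
    config = config, params = params, data = data),
    class = "clone_tree_fit")
}
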