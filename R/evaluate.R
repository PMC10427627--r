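#' Map inferred nodes to true nodes by genotype similarity
#'
#' Each inferred node is mapped to the true node with the most similar
#' genotype: the Hamming distance over per-variant `(c_ref, c_alt)` pairs
#' plus the Hamming distance over per-region copy numbers.  Ties go to the
#' smaller true node id.
#'
#' @param inferred,truth [event_tree]s over the same variant/region
#'   universe.
#' @param data a [panel_data] object.
#' @return Integer vector: for each inferred node, the mapped true node id.
#' @export
map_nodes_by_genotype <- function(inferred, truth, data) {
  gi <- genotypes_all(inferred, data)
  gt <- genotypes_all(truth, data)
  vapply(seq_len(n_nodes(inferred)), function(a) {
    d <- vapply(seq_len(n_nodes(truth)), function(b) {
      sum(gi$cr[a, ] != gt$cr[b, ] | gi$ca[a, ] != gt$ca[b, ]) +
        sum(gi$region_cn[a, ] != gt$region_cn[b, ])
    }, 0)
    which.min(d) # ties: smallest true id
  }, 0L)
}

#' Fraction of cells assigned to the right clone
#'
#' Doublet cells are excluded.  A cell counts as correct when its
#' maximum-a-posteriori inferred node maps (by genotype) to its true node.
#'
#' @param responsibilities inferred attachment posteriors (cells x
#'   attachments; doublet columns, if any, after the singlet columns).
#' @param truth ground-truth list from [simulate_cells()].
#' @param node_map mapping from [map_nodes_by_genotype()].
#' @return A fraction in `[0, 1]`.
#' @export
cell_assignment_accuracy <- function(responsibilities, truth, node_map) {
  n_sing <- length(node_map)
  map_col <- max.col(responsibilities, ties.method = "first")
  singlets <- !truth$is_doublet & map_col <= n_sing
  keep <- !truth$is_doublet
  correct <- singlets & node_map[pmin(map_col, n_sing)] == truth$attachment
  sum(correct[keep]) / sum(keep)
}

# CNA labels of a tree: "region:kind" strings (one per distinct call)
cna_labels <- function(tree) {
  cnas <- cna_placements(tree)
  if (nrow(cnas) == 0L) return(character(0))
  unique(paste0(cnas$region, ":", cnas$kind))
}

#' False positive and negative rates of the CNA calls
#'
#' A CNA call is identified by its region and kind (gain/loss/CNLOH).
#' `fnr` is the fraction of true calls missed; `fpr` the fraction of false
#' calls among the non-true label universe (`n_regions x 3 kinds` minus
#' the true calls).  The FNR is additionally stratified by whether the
#' true CNA is supported by an SNV or LOH at or below its node
#' ([classify_cna_support()]).
#'
#' @param inferred,truth [event_tree]s.
#' @param data a [panel_data] object.
#' @return A list with `fpr`, `fnr`, `fnr_supported`, `fnr_unsupported`
#'   (the latter two `NaN` when the stratum is empty).
#' @export
cna_calls_fpr_fnr <- function(inferred, truth, data) {
  li <- cna_labels(inferred)
  cnas_t <- cna_placements(truth)
  lt <- cna_labels(truth)
  universe <- nrow(data$regions) * 3
  fp <- length(setdiff(li, lt))
  fn <- length(setdiff(lt, li))
  fpr <- if (universe - length(lt) > 0) fp / (universe - length(lt)) else 0
  fnr <- if (length(lt) > 0) fn / length(lt) else 0

  sup <- classify_cna_support(truth, data)
  strat <- function(labels) {
    if (length(labels) == 0L) return(NaN)
    sum(!(labels %in% li)) / length(labels)
  }
  sup_lab <- if (any(sup))
    unique(paste0(cnas_t$region, ":", cnas_t$kind)[sup]) else character(0)
  uns_lab <- setdiff(lt, sup_lab)
  list(fpr = fpr, fnr = fnr, fnr_supported = strat(sup_lab),
       fnr_unsupported = strat(uns_lab))
}

#' Flag CNAs supported by SNVs or LOH
#'
#' A CNA is supported when its node, or any descendant, carries an SNV
#' event or an LOH-producing event (any CNLOH, or a loss removing the last
#' copy of some variant allele) — such CNAs are corroborated by allelic
#' signal rather than depth alone.
#'
#' @param tree an [event_tree].
#' @param data a [panel_data] object.
#' @return Logical vector, one flag per CNA event (tree traversal order).
#' @export
classify_cna_support <- function(tree, data) {
  cnas <- cna_placements(tree)
  if (nrow(cnas) == 0L) return(logical(0))
  vapply(seq_len(nrow(cnas)), function(r)
    subtree_has_support(tree, data, cnas$node[r]), TRUE)
}

#' Exact one-sided association test for a 2x2 table
#'
#' Fisher's exact test (hypergeometric tail, alternative "greater"), with
#' the odds ratio as the conditional maximum-likelihood estimate under the
#' noncentral hypergeometric model and the one-sided 95% confidence lower
#' bound from inverting the exact test.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return A list with `p_one_sided`, `odds_ratio_cmle`, `ci_95_lower`.
#' @export
exact_2x2_association <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L), all(table >= 0),
            all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin in 2x2 table", call. = FALSE)
  ft <- fisher.test(table, alternative = "greater", conf.level = 0.95)
  list(p_one_sided = unname(ft$p.value),
       odds_ratio_cmle = unname(ft$estimate),
       ci_95_lower = unname(ft$conf.int[1L]))
}

#' Score an inferred tree against simulation ground truth
#'
#' @param fit a [fit_clone_tree()] result (or a list with `tree` and
#'   `responsibilities`).
#' @param truth ground truth from [simulate_cells()].
#' @param data the [panel_data] the fit used.
#' @return A list of class `eval_report`: `cell_assignment_accuracy`,
#'   `cna_fpr`, `cna_fnr`, `cna_fnr_supported`, `cna_fnr_unsupported`,
#'   `snv_placement_accuracy` (fraction of variants whose inferred node
#'   maps to their true node), `node_map`.
#' @export
evaluate_fit <- function(fit, truth, data) {
  node_map <- map_nodes_by_genotype(fit$tree, truth$tree, data)
  acc <- cell_assignment_accuracy(fit$responsibilities, truth, node_map)
  rates <- cna_calls_fpr_fnr(fit$tree, truth$tree, data)

  snv_i <- snv_placements(fit$tree)
  snv_t <- snv_placements(truth$tree)
  common <- intersect(snv_i$variant, snv_t$variant)
  snv_acc <- if (length(common) == 0L) NaN else
    mean(vapply(common, function(v)
      node_map[snv_i$node[snv_i$variant == v][1L]] ==
        snv_t$node[snv_t$variant == v][1L], TRUE))

  structure(list(cell_assignment_accuracy = acc, cna_fpr = rates$fpr,
                 cna_fnr = rates$fnr,
                 cna_fnr_supported = rates$fnr_supported,
                 cna_fnr_unsupported = rates$fnr_unsupported,
                 snv_placement_accuracy = snv_acc, node_map = node_map),
            class = "eval_report")
}
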