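# does a CNA event produce LOH at any of its variants?  Needs the genotype
# immediately before the event on that node's root path.
event_is_loh <- function(e, geno_before, data) {
  if (e$kind == "CNLOH") return(TRUE)
  if (e$kind != "LOSS") return(FALSE)
  vars_k <- which(data$variants$region == e$target)
  for (i in vars_k) {
    a <- e$alleles[[as.character(i)]]
    cur <- if (a == "ref") geno_before$cr[i] else geno_before$ca[i]
    if (cur == 1) return(TRUE) # last copy of that allele removed
  }
  FALSE
}

# per-node pre-event genotype replay yielding, for every CNA event, its
# (node, region, kind, loh) record
cna_event_records <- function(tree, data) {
  genos <- vector("list", n_nodes(tree))
  out <- list()
  for (nd in node_order(tree)) {
    g <- if (nd == 1L) root_genotype(data) else genos[[tree$parent[nd]]]
    for (e in ordered_events(tree$events[[nd]])) {
      if (e$kind != "SNV")
        out[[length(out) + 1L]] <-
          data.frame(node = nd, region = e$target, kind = e$kind,
                     loh = event_is_loh(e, g, data))
      g <- apply_event(g, e, data)$geno
    }
    genos[[nd]] <- g
  }
  if (length(out) == 0L)
    return(data.frame(node = integer(0), region = integer(0),
                      kind = character(0), loh = logical(0)))
  do.call(rbind, out)
}

#' Count CNA events with contiguous-region merging
#'
#' Within a node, CNA events of the same kind on regions that are adjacent
#' in genomic order (same chromosome, consecutive `order_index`) are
#' counted as a single event, because real alterations typically span
#' large genomic stretches, often whole chromosomes.  A merged event counts
#' as LOH if any constituent produces LOH (a variant allele dropping to
#' zero copies, or any CNLOH).
#'
#' @param tree an [event_tree].
#' @param data a [panel_data] object (supplies region adjacency).
#' @return `c(n_cna_loh = ..., n_cna_no_loh = ...)`.
#' @export
count_cna_events <- function(tree, data) {
  rec <- cna_event_records(tree, data)
  if (nrow(rec) == 0L) return(c(n_cna_loh = 0L, n_cna_no_loh = 0L))
  rec$chrom <- data$regions$chrom[rec$region]
  rec$ord <- data$regions$order_index[rec$region]
  n_loh <- 0L; n_no <- 0L
  for (key in unique(paste(rec$node, rec$kind, rec$chrom))) {
    parts <- strsplit(key, " ")[[1L]]
    sel <- rec[rec$node == as.integer(parts[1L]) & rec$kind == parts[2L] &
                 rec$chrom == parts[3L], , drop = FALSE]
    sel <- sel[order(sel$ord), , drop = FALSE]
    grp <- cumsum(c(1L, diff(sel$ord) > 1L))
    for (g in unique(grp)) {
      if (any(sel$loh[grp == g])) n_loh <- n_loh + 1L
      else n_no <- n_no + 1L
    }
  }
  c(n_cna_loh = n_loh, n_cna_no_loh = n_no)
}

#' Log-prior of an event tree (up to an additive constant)
#'
#' Three penalty terms: `-p1 * n_muts * n_nodes` (tree size; `n_muts`
#' counts SNV events, `n_nodes` includes the root),
#' `-(1500 + n_cells) * p2 * (n_cna_loh + n_cna_no_loh / 2)` (copy-number
#' events after contiguous merging, LOH-producing ones penalised twice as
#' much, with an affine cell-count scaling so that more cells demand no
#' less evidence per event), and for every variant placed away from the
#' root `-(p3 + p4 * pop_freq)` (population-frequent variants are most
#' likely germline and resist somatic placement; absent frequencies count
#' as zero).
#'
#' @param tree an [event_tree].
#' @param data a [panel_data] object.
#' @param penalties a [prior_penalties] object.
#' @param n_cells number of cells (defaults to the panel's).
#' @return The log-prior, dropping the normalising constant.
#' @export
tree_log_prior <- function(tree, data, penalties = prior_penalties(),
                           n_cells = length(data$cell_ids)) {
  snvs <- snv_placements(tree)
  n_muts <- nrow(snvs)
  lp <- -penalties$p1 * n_muts * n_nodes(tree)

  cnt <- count_cna_events(tree, data)
  lp <- lp - (1500 + n_cells) * penalties$p2 *
    (cnt[["n_cna_loh"]] + cnt[["n_cna_no_loh"]] / 2)

  off_root <- snvs$variant[snvs$node != 1L]
  if (length(off_root) > 0L) {
    freq <- data$variants$pop_freq[off_root]
    freq[is.na(freq)] <- 0
    lp <- lp - sum(penalties$p3 + penalties$p4 * freq)
  }
  unname(lp)
}
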