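#' Rooted trees of somatic events
#'
#' An event tree is a rooted tree whose nodes carry ordered sets of somatic
#' events.  Four event kinds are supported: `SNV` (a point mutation,
#' acquired exactly once in the whole tree), and the allele-specific
#' copy-number alterations `GAIN`, `LOSS` and `CNLOH` (at most one CNA per
#' region per root-to-leaf lineage).  Each node implies a genotype, obtained
#' by applying the events on its root path to the diploid genome; within a
#' node, SNVs are applied before CNAs, ties broken by target index, so that
#' e.g. an SNV co-located with a CNLOH is acquired before the copy event.
#'
#' Node 1 is always the root.  Events are lists with elements `kind`
#' (`"SNV"`, `"GAIN"`, `"LOSS"`, `"CNLOH"`), `target` (1-based variant index
#' for SNVs, region index for CNAs) and, for CNAs on variant-bearing
#' regions, `alleles`: a character vector (`"ref"`/`"alt"`) named by the
#' indices of the variants in the region, giving which allele the event
#' affects at each locus.
#'
#' @param parent integer vector of parent node ids; entry 1 must be `NA`
#'   (the root), every other entry a valid node id.
#' @param events list (one element per node) of lists of events; `list()`
#'   for event-free nodes.
#' @return An object of class `event_tree`.
#' @export
event_tree <- function(parent, events = NULL) {
  parent <- as.integer(parent)
  n <- length(parent)
  if (n < 1L || !is.na(parent[1L]))
    stop("node 1 must be the root (parent NA)", call. = FALSE)
  if (n > 1L && any(is.na(parent[-1L])))
    stop("only the root may have parent NA", call. = FALSE)
  if (n > 1L && (any(parent[-1L] < 1L) || any(parent[-1L] > n)))
    stop("parent ids out of range", call. = FALSE)
  # reachability check (also catches cycles)
  reached <- rep(FALSE, n)
  reached[1L] <- TRUE
  frontier <- 1L
  while (length(frontier) > 0L) {
    nxt <- which(parent %in% frontier & !reached)
    reached[nxt] <- TRUE
    frontier <- nxt
  }
  if (!all(reached))
    stop("parent vector does not describe a connected rooted tree",
         call. = FALSE)
  if (is.null(events)) events <- rep(list(list()), n)
  if (length(events) != n)
    stop("events must have one entry per node", call. = FALSE)
  structure(list(parent = parent, events = events), class = "event_tree")
}

n_nodes <- function(tree) length(tree$parent)

new_event <- function(kind, target, alleles = NULL) {
  list(kind = kind, target = as.integer(target), alleles = alleles)
}

tree_children <- function(tree) {
  lapply(seq_len(n_nodes(tree)), function(i) which(tree$parent == i))
}

# nodes in root-first (topological) order
node_order <- function(tree) {
  n <- n_nodes(tree)
  ord <- integer(0)
  frontier <- 1L
  while (length(frontier) > 0L) {
    ord <- c(ord, frontier)
    frontier <- which(tree$parent %in% frontier)
  }
  ord
}

# descendant sets (including the node itself)
tree_subtree <- function(tree, node) {
  sub <- node
  frontier <- node
  while (length(frontier) > 0L) {
    frontier <- which(tree$parent %in% frontier)
    sub <- c(sub, frontier)
  }
  sub
}

# events of one node in canonical application order: SNVs first, then CNAs,
# ties broken by target index
ordered_events <- function(evts) {
  if (length(evts) == 0L) return(evts)
  kinds <- vapply(evts, `[[`, "", "kind")
  targets <- vapply(evts, function(e) as.integer(e$target), 0L)
  evts[order(kinds != "SNV", targets)]
}

# all SNV events in the tree: data.frame(node, variant)
snv_placements <- function(tree) {
  out <- list()
  for (nd in seq_len(n_nodes(tree)))
    for (e in tree$events[[nd]])
      if (e$kind == "SNV")
        out[[length(out) + 1L]] <- c(nd, e$target)
  if (length(out) == 0L)
    return(data.frame(node = integer(0), variant = integer(0)))
  m <- do.call(rbind, out)
  data.frame(node = m[, 1L], variant = m[, 2L])
}

# all CNA events: data.frame(node, region, kind, event_index)
cna_placements <- function(tree) {
  out <- list()
  for (nd in seq_len(n_nodes(tree))) {
    for (k in seq_along(tree$events[[nd]])) {
      e <- tree$events[[nd]][[k]]
      if (e$kind != "SNV")
        out[[length(out) + 1L]] <-
          data.frame(node = nd, region = e$target, kind = e$kind,
                     event_index = k)
    }
  }
  if (length(out) == 0L)
    return(data.frame(node = integer(0), region = integer(0),
                      kind = character(0), event_index = integer(0)))
  do.call(rbind, out)
}

# apply one event to a genotype; returns list(geno, violations)
apply_event <- function(geno, e, data) {
  viol <- character(0)
  if (e$kind == "SNV") {
    i <- e$target
    if (geno$cr[i] < 1) {
      viol <- sprintf("allele absent: no REF copy to mutate for variant %d", i)
    } else {
      geno$cr[i] <- geno$cr[i] - 1
      geno$ca[i] <- geno$ca[i] + 1
    }
    return(list(geno = geno, violations = viol))
  }
  k <- e$target
  vars_k <- which(data$variants$region == k)
  alle <- e$alleles
  if (length(vars_k) > 0L) {
    if (is.null(alle) || !setequal(names(alle), as.character(vars_k)))
      return(list(geno = geno, violations = sprintf(
        "malformed event: CNA on region %d must specify alleles for variants %s",
        k, paste(vars_k, collapse = ","))))
  }
  if (e$kind == "GAIN") {
    if (geno$region_cn[k] + 1 > 3) {
      viol <- c(viol, sprintf("copy-number cap: gain on region %d exceeds 3", k))
    }
    geno$region_cn[k] <- geno$region_cn[k] + 1
    for (i in vars_k) {
      a <- alle[[as.character(i)]]
      cur <- if (a == "ref") geno$cr[i] else geno$ca[i]
      if (cur < 1)
        viol <- c(viol, sprintf(
          "allele absent: cannot gain %s allele of variant %d", a, i))
      if (a == "ref") geno$cr[i] <- geno$cr[i] + 1
      else geno$ca[i] <- geno$ca[i] + 1
    }
  } else if (e$kind == "LOSS") {
    if (geno$region_cn[k] < 1)
      viol <- c(viol, sprintf("copy-number cap: loss on empty region %d", k))
    geno$region_cn[k] <- max(geno$region_cn[k] - 1, 0)
    for (i in vars_k) {
      a <- alle[[as.character(i)]]
      cur <- if (a == "ref") geno$cr[i] else geno$ca[i]
      if (cur < 1)
        viol <- c(viol, sprintf(
          "allele absent: cannot lose %s allele of variant %d", a, i))
      if (a == "ref") geno$cr[i] <- max(geno$cr[i] - 1, 0)
      else geno$ca[i] <- max(geno$ca[i] - 1, 0)
    }
  } else if (e$kind == "CNLOH") {
    # the affected allele is replaced by the other allele; totals unchanged
    for (i in vars_k) {
      a <- alle[[as.character(i)]]
      cur <- if (a == "ref") geno$cr[i] else geno$ca[i]
      if (cur < 1)
        viol <- c(viol, sprintf(
          "allele absent: CNLOH removing absent %s allele of variant %d", a, i))
      tot <- geno$cr[i] + geno$ca[i]
      if (a == "ref") { geno$cr[i] <- 0; geno$ca[i] <- tot }
      else { geno$ca[i] <- 0; geno$cr[i] <- tot }
    }
  } else {
    viol <- c(viol, sprintf("malformed event: unknown kind '%s'", e$kind))
  }
  list(geno = geno, violations = viol)
}

root_genotype <- function(data) {
  list(region_cn = rep(2, nrow(data$regions)),
       cr = rep(2, nrow(data$variants)),
       ca = rep(0, nrow(data$variants)))
}

# replay genotypes for every node; returns list(region_cn, cr, ca matrices
# [n_nodes x .], violations)
genotypes_all <- function(tree, data) {
  n <- n_nodes(tree)
  nr <- nrow(data$regions)
  nv <- nrow(data$variants)
  region_cn <- matrix(NA_real_, n, nr)
  cr <- matrix(NA_real_, n, nv)
  ca <- matrix(NA_real_, n, nv)
  viol <- character(0)
  genos <- vector("list", n)
  for (nd in node_order(tree)) {
    g <- if (nd == 1L) root_genotype(data) else genos[[tree$parent[nd]]]
    for (e in ordered_events(tree$events[[nd]])) {
      res <- apply_event(g, e, data)
      g <- res$geno
      if (length(res$violations) > 0L)
        viol <- c(viol, paste0("node ", nd, ": ", res$violations))
    }
    genos[[nd]] <- g
    region_cn[nd, ] <- g$region_cn
    cr[nd, ] <- g$cr
    ca[nd, ] <- g$ca
  }
  list(region_cn = region_cn, cr = cr, ca = ca, violations = viol)
}

#' Derive the genotype implied by a tree node
#'
#' Applies the events on the root path of `node` to the wild-type diploid
#' genome.  SNVs convert one REF copy to ALT; `GAIN`/`LOSS` add or remove
#' one copy of the chosen allele (and of the region); `CNLOH` transfers all
#' copies of the affected allele to the other allele, leaving the region
#' copy number unchanged.
#'
#' @param tree an [event_tree].
#' @param node node id.
#' @param data a [panel_data] object supplying the variant/region universe.
#' @return A list with `region_cn` (per-region copy numbers), `cr` and `ca`
#'   (per-variant REF and ALT allele copy numbers).
#' @export
node_genotype <- function(tree, node, data) {
  g <- genotypes_all(tree, data)
  if (length(g$violations) > 0L)
    stop("invalid tree: ", g$violations[1L], call. = FALSE)
  list(region_cn = g$region_cn[node, ], cr = g$cr[node, ], ca = g$ca[node, ])
}

#' Combined genotype of a doublet
#'
#' Allele copy numbers of the two nodes are summed; region copy numbers are
#' averaged (and may therefore be non-integer).
#'
#' @param g1,g2 genotypes as returned by [node_genotype()].
#' @return A genotype list of the same shape.
#' @export
doublet_genotype <- function(g1, g2) {
  list(region_cn = (g1$region_cn + g2$region_cn) / 2,
       cr = g1$cr + g2$cr, ca = g1$ca + g2$ca)
}

#' Check an event tree against its combinatorial constraints
#'
#' Verifies, against the variant/region universe of `data`, that every SNV
#' is placed exactly once, that no root-to-leaf lineage carries more than
#' one CNA on the same region, that every CNA affects an allele present in
#' the pre-event genotype, and that region copy numbers stay within
#' `{0,...,3}`.
#'
#' @param tree an [event_tree].
#' @param data a [panel_data] object.
#' @return A character vector of violation messages; `character(0)` if the
#'   tree is valid.
#' @export
validate_tree <- function(tree, data) {
  viol <- character(0)
  nv <- nrow(data$variants)
  nr <- nrow(data$regions)

  snvs <- snv_placements(tree)
  if (any(snvs$variant < 1L | snvs$variant > nv))
    viol <- c(viol, "malformed event: SNV target out of range")
  tab <- tabulate(snvs$variant, nbins = nv)
  for (i in which(tab > 1L))
    viol <- c(viol, sprintf("SNV multiplicity: variant %d placed %d times",
                            i, tab[i]))
  for (i in which(tab == 0L))
    viol <- c(viol, sprintf("SNV missing: variant %d not placed", i))

  cnas <- cna_placements(tree)
  if (nrow(cnas) > 0L && any(cnas$region < 1L | cnas$region > nr))
    return(c(viol, "malformed event: CNA target out of range"))
  # at most one CNA per region per lineage: walk every root path
  if (nrow(cnas) > 0L) {
    counts_above <- matrix(0L, n_nodes(tree), nr)
    for (nd in node_order(tree)) {
      cnt <- if (nd == 1L) rep(0L, nr) else counts_above[tree$parent[nd], ]
      cnt <- cnt + tabulate(cnas$region[cnas$node == nd], nbins = nr)
      if (any(cnt > 1L))
        viol <- c(viol, sprintf(
          "CNA per lineage: region %d altered more than once on the path to node %d",
          which(cnt > 1L)[1L], nd))
      counts_above[nd, ] <- cnt
    }
  }

  g <- genotypes_all(tree, data)
  viol <- c(viol, g$violations)
  if (any(g$region_cn > 3 | g$region_cn < 0))
    viol <- c(viol, "copy-number cap: region copy number outside {0,...,3}")
  unique(viol)
}

#' @export
print.event_tree <- function(x, ...) {
  cat(sprintf("event_tree with %d node(s)\n", n_nodes(x)))
  for (nd in node_order(x)) {
    evts <- vapply(x$events[[nd]], function(e) {
      if (e$kind == "SNV") sprintf("SNV(v%d)", e$target)
      else sprintf("%s(r%d)", e$kind, e$target)
    }, "")
    lab <- if (length(evts) == 0L) "-" else paste(evts, collapse = " ")
    par <- if (nd == 1L) "root" else sprintf("parent %d", x$parent[nd])
    cat(sprintf("  node %d (%s): %s\n", nd, par, lab))
  }
  invisible(x)
}
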