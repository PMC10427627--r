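#' Serialise an event tree to JSON or GraphViz DOT
#'
#' The JSON dialect stores nodes with 0-based ids (`0` = root), parent
#' pointers, event lists (each event: `kind`, `variant` or `region` id,
#' and per-variant `alleles` for CNAs on variant-bearing regions) and node
#' weights.  The DOT format draws one box per node listing its events, an
#' edge to its parent and the node weight as a percentage.
#'
#' @param tree an [event_tree].
#' @param pi node weight vector aligned to nodes.
#' @param path output file path.
#' @param data a [panel_data] object (supplies variant/region ids).
#' @param format `"json"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, pi, path, data, format = c("json", "dot")) {
  format <- match.arg(format)
  n <- n_nodes(tree)
  stopifnot(length(pi) == n)
  event_label <- function(e) {
    if (e$kind == "SNV") data$variants$id[e$target]
    else paste0(e$kind, " ", data$regions$id[e$target])
  }
  if (format == "json") {
    nodes <- lapply(seq_len(n), function(nd) {
      evts <- lapply(tree$events[[nd]], function(e) {
        if (e$kind == "SNV") {
          list(kind = "SNV", variant = data$variants$id[e$target])
        } else {
          out <- list(kind = e$kind, region = data$regions$id[e$target])
          if (!is.null(e$alleles) && length(e$alleles) > 0L)
            out$alleles <- as.list(setNames(
              unname(e$alleles),
              data$variants$id[as.integer(names(e$alleles))]))
          out
        }
      })
      list(id = nd - 1L,
           parent = if (nd == 1L) -1L else tree$parent[nd] - 1L,
           events = evts, weight = pi[nd])
    })
    jsonlite::write_json(list(nodes = nodes), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    lines <- c("digraph clonetree {", "  node [shape=box];")
    for (nd in seq_len(n)) {
      evts <- vapply(tree$events[[nd]], event_label, "")
      lab <- if (length(evts) == 0L) "(no events)" else
        paste(evts, collapse = "\\n")
      lines <- c(lines, sprintf("  n%d [label=\"%s\\n%.1f%%\"];",
                                nd - 1L, lab, 100 * pi[nd]))
    }
    for (nd in seq_len(n)[-1L])
      lines <- c(lines, sprintf("  n%d -> n%d;", tree$parent[nd] - 1L,
                                nd - 1L))
    lines <- c(lines, "}")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read an event tree written by [write_tree()] (JSON dialect)
#'
#' @param path JSON file path.
#' @param data the [panel_data] whose variant/region ids the tree refers to.
#' @return A list with `tree` (an [event_tree]) and `pi` (node weights).
#' @export
read_tree <- function(path, data) {
  obj <- jsonlite::read_json(path)
  nodes <- obj$nodes
  ids <- vapply(nodes, function(x) x$id, 0) + 1L
  ord <- order(ids)
  nodes <- nodes[ord]
  parent <- vapply(nodes, function(x) x$parent, 0) + 1L
  parent[parent == 0L] <- NA_integer_
  events <- lapply(nodes, function(x) {
    lapply(x$events, function(e) {
      if (e$kind == "SNV") {
        new_event("SNV", match(e$variant, data$variants$id))
      } else {
        alle <- NULL
        if (!is.null(e$alleles)) {
          idx <- match(names(e$alleles), data$variants$id)
          alle <- setNames(unlist(e$alleles, use.names = FALSE),
                           as.character(idx))
        }
        new_event(e$kind, match(e$region, data$regions$id), alle)
      }
    })
  })
  pi <- vapply(nodes, function(x) x$weight, 0)
  list(tree = event_tree(parent, events), pi = pi)
}

#' Write per-cell attachment posteriors
#'
#' One row per cell: the maximum-a-posteriori attachment (node id, or
#' `"a+b"` for a doublet pair) followed by the full posterior over
#' attachments.  Rows must sum to 1.
#'
#' @param responsibilities matrix `[n_cells x n_attachments]` of posterior
#'   attachment probabilities; row names are cell ids.
#' @param path output CSV path.
#' @param pairs optional 2-column matrix labelling doublet columns.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(responsibilities, path, pairs = NULL) {
  rs <- rowSums(responsibilities)
  if (any(abs(rs - 1) > 1e-6))
    stop("responsibility rows must sum to 1 (max deviation ",
         signif(max(abs(rs - 1)), 3), ")", call. = FALSE)
  n <- ncol(responsibilities) - if (is.null(pairs)) 0L else nrow(pairs)
  labels <- paste0("node", seq_len(n))
  if (!is.null(pairs))
    labels <- c(labels, paste0("node", pairs[, 1L], "+node", pairs[, 2L]))
  map <- labels[max.col(responsibilities, ties.method = "first")]
  df <- data.frame(
    cell = rownames(responsibilities) %||%
      paste0("cell_", seq_len(nrow(responsibilities))),
    map_attachment = map, responsibilities, check.names = FALSE)
  colnames(df)[-(1:2)] <- labels
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read attachment posteriors written by [write_assignments()]
#'
#' @param path CSV path.
#' @return A list with `responsibilities` (numeric matrix, cell ids as row
#'   names) and `map` (character vector of MAP attachment labels).
#' @export
read_assignments <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  resp <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(resp) <- df$cell
  list(responsibilities = resp, map = df$map_attachment)
}
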