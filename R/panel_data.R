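#' Per-cell read counts from a targeted single-cell panel
#'
#' `panel_data()` bundles the two count layers produced by amplicon-based
#' single-cell DNA sequencing: the total read depth of every cell in every
#' panel region (a region is a gene, i.e. the group of amplicons targeting
#' that gene), and the REF/ALT read counts of every cell at every variable
#' locus.  Both layers are validated against each other and against the
#' variant/region metadata.
#'
#' Cells whose total read count is zero carry no information (the depth
#' model conditions on the per-cell total) and are dropped with a warning.
#'
#' @param region_depth integer matrix `[n_cells x n_regions]` of reads per
#'   cell per region; row names are cell ids, column names region ids.
#' @param alt_counts,var_depth integer matrices `[n_cells x n_variants]` of
#'   ALT-supporting reads and total reads at each variable locus; column
#'   names are variant ids.
#' @param variants data frame with columns `id`, `region` (region id or
#'   1-based region index), `chrom`, `pos` and optionally `pop_freq`
#'   (population allele frequency in `[0,1]`, `NA` for somatic variants).
#' @param regions data frame with columns `id`, `chrom`, `order_index`
#'   (genomic order within the chromosome), `n_amplicons` and optionally
#'   `usable_for_cna` (logical, default `TRUE`).
#' @return An object of class `panel_data`: a list with elements
#'   `region_depth`, `cell_total`, `alt_counts`, `var_depth`, `cell_ids`,
#'   `variants`, `regions`.
#' @export
panel_data <- function(region_depth, alt_counts, var_depth, variants, regions) {
  region_depth <- as.matrix(region_depth)
  alt_counts <- as.matrix(alt_counts)
  var_depth <- as.matrix(var_depth)

  check_counts <- function(m, what) {
    if (any(is.na(m)))
      stop(sprintf("%s contains missing values", what), call. = FALSE)
    if (any(m < 0) || any(m != round(m)))
      stop(sprintf("%s must contain non-negative integers", what), call. = FALSE)
    storage.mode(m) <- "integer"
    m
  }
  region_depth <- check_counts(region_depth, "region_depth")
  alt_counts <- check_counts(alt_counts, "alt_counts")
  var_depth <- check_counts(var_depth, "var_depth")

  regions <- as.data.frame(regions, stringsAsFactors = FALSE)
  for (col in c("id", "chrom", "order_index", "n_amplicons"))
    if (is.null(regions[[col]]))
      stop("region metadata lacks column '", col, "'", call. = FALSE)
  if (is.null(regions$usable_for_cna)) regions$usable_for_cna <- TRUE
  regions$id <- as.character(regions$id)
  if (anyDuplicated(regions$id))
    stop("duplicated region ids in metadata", call. = FALSE)
  if (any(regions$n_amplicons < 1))
    stop("every region must have n_amplicons >= 1", call. = FALSE)
  dup_ord <- stats::aggregate(order_index ~ chrom, regions,
                              function(x) anyDuplicated(x) > 0)
  if (any(dup_ord$order_index))
    stop("order_index must be unique within each chromosome", call. = FALSE)

  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  for (col in c("id", "region", "chrom", "pos"))
    if (is.null(variants[[col]]))
      stop("variant metadata lacks column '", col, "'", call. = FALSE)
  if (is.null(variants$pop_freq)) variants$pop_freq <- NA_real_
  variants$id <- as.character(variants$id)
  if (is.character(variants$region) || is.factor(variants$region)) {
    idx <- match(as.character(variants$region), regions$id)
  } else {
    idx <- as.integer(variants$region)
    idx[idx < 1L | idx > nrow(regions)] <- NA_integer_
  }
  if (any(is.na(idx)))
    stop("variant(s) ", paste(variants$id[is.na(idx)], collapse = ", "),
         " reference an unknown region", call. = FALSE)
  variants$region <- idx
  bad_freq <- !is.na(variants$pop_freq) &
    (variants$pop_freq < 0 | variants$pop_freq > 1)
  if (any(bad_freq))
    stop("pop_freq must lie in [0,1]", call. = FALSE)

  if (ncol(region_depth) != nrow(regions))
    stop(sprintf("region_depth has %d columns but %d regions are described",
                 ncol(region_depth), nrow(regions)), call. = FALSE)
  if (ncol(alt_counts) != nrow(variants) || ncol(var_depth) != nrow(variants))
    stop("variant count matrices do not match the number of variants",
         call. = FALSE)
  if (nrow(alt_counts) != nrow(region_depth) ||
      nrow(var_depth) != nrow(region_depth))
    stop(sprintf(paste0("cell dimension mismatch: region_depth has %d cells, ",
                        "alt_counts %d, var_depth %d"),
                 nrow(region_depth), nrow(alt_counts), nrow(var_depth)),
         call. = FALSE)

  cell_ids <- rownames(region_depth) %||%
    paste0("cell_", seq_len(nrow(region_depth)))
  other_ids <- rownames(alt_counts)
  if (!is.null(other_ids) && !identical(other_ids, cell_ids)) {
    missing <- setdiff(union(cell_ids, other_ids),
                       intersect(cell_ids, other_ids))
    stop("cells present in one matrix but not the other: ",
         paste(head(missing, 5L), collapse = ", "), call. = FALSE)
  }

  over <- which(alt_counts > var_depth, arr.ind = TRUE)
  if (nrow(over) > 0L) {
    stop(sprintf("ALT count exceeds locus depth for cell '%s', variant '%s'",
                 cell_ids[over[1L, 1L]], variants$id[over[1L, 2L]]),
         call. = FALSE)
  }

  cell_total <- as.integer(rowSums(region_depth))
  keep <- cell_total > 0L
  if (!all(keep)) {
    warning(sum(!keep), " cell(s) with zero total reads dropped", call. = FALSE)
    region_depth <- region_depth[keep, , drop = FALSE]
    alt_counts <- alt_counts[keep, , drop = FALSE]
    var_depth <- var_depth[keep, , drop = FALSE]
    cell_total <- cell_total[keep]
    cell_ids <- cell_ids[keep]
  }
  rownames(region_depth) <- rownames(alt_counts) <- rownames(var_depth) <- cell_ids
  colnames(region_depth) <- regions$id
  colnames(alt_counts) <- colnames(var_depth) <- variants$id

  structure(
    list(region_depth = region_depth, cell_total = cell_total,
         alt_counts = alt_counts, var_depth = var_depth,
         cell_ids = cell_ids, variants = variants, regions = regions),
    class = "panel_data")
}

#' @export
print.panel_data <- function(x, ...) {
  cat(sprintf("panel_data: %d cells, %d regions, %d variants\n",
              length(x$cell_ids), nrow(x$regions), nrow(x$variants)))
  cat(sprintf("  median reads/cell: %.0f; germline-candidate variants: %d\n",
              stats::median(x$cell_total), sum(!is.na(x$variants$pop_freq))))
  invisible(x)
}

#' @export
dim.panel_data <- function(x) {
  c(cells = length(x$cell_ids), regions = nrow(x$regions),
    variants = nrow(x$variants))
}

#' Read panel count matrices and metadata from delimited files
#'
#' The canonical on-disk layout is four CSV files: region counts (first
#' column `cell`, one column per region id), variant counts (first column
#' `cell`, two columns `<variant>_ref` and `<variant>_alt` per variant),
#' variant metadata and region metadata (see [panel_data()] for columns).
#'
#' @param region_counts_path,variant_counts_path,variant_meta_path,region_meta_path
#'   paths to the four files.
#' @return A validated [panel_data] object.
#' @export
load_panel_data <- function(region_counts_path, variant_counts_path,
                            variant_meta_path, region_meta_path) {
  for (p in c(region_counts_path, variant_counts_path,
              variant_meta_path, region_meta_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)

  rc <- read.csv(region_counts_path, check.names = FALSE,
                 stringsAsFactors = FALSE)
  vc <- read.csv(variant_counts_path, check.names = FALSE,
                 stringsAsFactors = FALSE)
  vmeta <- read.csv(variant_meta_path, stringsAsFactors = FALSE)
  rmeta <- read.csv(region_meta_path, stringsAsFactors = FALSE)
  if (names(rc)[1L] != "cell" || names(vc)[1L] != "cell")
    stop("count files must have 'cell' as their first column", call. = FALSE)

  region_depth <- as.matrix(rc[, -1L, drop = FALSE])
  rownames(region_depth) <- rc$cell

  ids <- as.character(vmeta$id)
  ref_cols <- paste0(ids, "_ref")
  alt_cols <- paste0(ids, "_alt")
  missing <- setdiff(c(ref_cols, alt_cols), names(vc))
  if (length(missing) > 0L)
    stop("variant count file lacks column(s): ",
         paste(head(missing, 5L), collapse = ", "), call. = FALSE)
  ref <- as.matrix(vc[, ref_cols, drop = FALSE])
  alt <- as.matrix(vc[, alt_cols, drop = FALSE])
  rownames(ref) <- rownames(alt) <- vc$cell
  if (!setequal(rc$cell, vc$cell))
    stop("cells present in one matrix but not the other: ",
         paste(head(setdiff(union(rc$cell, vc$cell),
                            intersect(rc$cell, vc$cell)), 5L), collapse = ", "),
         call. = FALSE)
  alt <- alt[rc$cell, , drop = FALSE]
  ref <- ref[rc$cell, , drop = FALSE]

  panel_data(region_depth = region_depth, alt_counts = alt,
             var_depth = ref + alt, variants = vmeta, regions = rmeta)
}

#' Write a panel_data object to the canonical CSV layout
#'
#' @param data a [panel_data] object.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_panel_data <- function(data, dir, prefix = "panel") {
  stopifnot(inherits(data, "panel_data"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    region_counts = file.path(dir, paste0(prefix, "_region_counts.csv")),
    variant_counts = file.path(dir, paste0(prefix, "_variant_counts.csv")),
    variant_meta = file.path(dir, paste0(prefix, "_variant_meta.csv")),
    region_meta = file.path(dir, paste0(prefix, "_region_meta.csv")))

  rc <- data.frame(cell = data$cell_ids, data$region_depth,
                   check.names = FALSE)
  write.csv(rc, paths["region_counts"], row.names = FALSE)

  ref <- data$var_depth - data$alt_counts
  vc <- data.frame(cell = data$cell_ids, check.names = FALSE)
  for (i in seq_len(nrow(data$variants))) {
    vc[[paste0(data$variants$id[i], "_ref")]] <- ref[, i]
    vc[[paste0(data$variants$id[i], "_alt")]] <- data$alt_counts[, i]
  }
  write.csv(vc, paths["variant_counts"], row.names = FALSE)

  vmeta <- data$variants
  vmeta$region <- data$regions$id[vmeta$region]
  write.csv(vmeta, paths["variant_meta"], row.names = FALSE)
  write.csv(data$regions, paths["region_meta"], row.names = FALSE)
  invisible(paths)
}
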