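#' UMI count matrix with per-cell metadata
#'
#' The basic container of the package: a sparse genes-by-cells matrix of
#' non-negative integer UMI counts together with a cell metadata table
#' (species, developmental stage, batch, and - for synthetic data -
#' ground-truth labels).
#'
#' @param counts genes x cells matrix (dense or sparse) of non-negative
#'   integer counts with unique rownames (gene ids) and colnames (cell ids).
#' @param cell_meta data.frame with one row per cell; typical columns are
#'   `species`, `stage`, `batch` and `truth_*` columns for synthetic data.
#' @return An object of class `count_matrix` with elements `counts`,
#'   `gene_ids`, `cell_ids`, `cell_meta`.
#' @export
count_matrix <- function(counts, cell_meta = NULL) {
  counts <- as(Matrix::Matrix(counts, sparse = TRUE) * 1, "CsparseMatrix")
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    stop("counts must have gene rownames and cell colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene_ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate cell_ids")
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x))))
    stop("counts must be non-negative integers")
  if (is.null(cell_meta))
    cell_meta <- data.frame(row.names = colnames(counts))
  if (nrow(cell_meta) != ncol(counts))
    stop("cell_meta rows must match number of cells")
  rownames(cell_meta) <- colnames(counts)
  structure(list(counts = counts,
                 gene_ids = rownames(counts),
                 cell_ids = colnames(counts),
                 cell_meta = cell_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  nz <- length(x$counts@x)
  cat(sprintf("count_matrix: %d genes x %d cells (%.1f%% sparse)\n",
              nrow(x$counts), ncol(x$counts),
              100 * (1 - nz / prod(dim(x$counts)))))
  if (ncol(x$cell_meta))
    cat("cell_meta:", paste(colnames(x$cell_meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by genes and/or cells
#'
#' @param m a `count_matrix`.
#' @param genes,cells index vectors (ids, integers or logicals); `NULL` keeps
#'   everything.
#' @return A `count_matrix` restricted to the selection.
#' @export
subset_cells <- function(m, genes = NULL, cells = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  counts <- m$counts
  if (!is.null(genes)) counts <- counts[genes, , drop = FALSE]
  if (!is.null(cells)) counts <- counts[, cells, drop = FALSE]
  count_matrix(counts, m$cell_meta[colnames(counts), , drop = FALSE])
}

#' Log-normalized expression matrix
#'
#' Container for per-cell depth-normalized, natural-log transformed
#' expression, as produced by [normalize_log()].
#'
#' @param values genes x cells matrix of ln(1 + scaled counts) values.
#' @param norm_kind `"lnTP10K"` (scale factor 10,000) or `"lnTP0.1M"`
#'   (100,000).
#' @param scale_factor the per-cell total the counts were scaled to.
#' @param cell_meta per-cell metadata carried over from the source counts.
#' @return An object of class `normalized_matrix`.
#' @export
normalized_matrix <- function(values, norm_kind, scale_factor,
                              cell_meta = NULL) {
  values <- Matrix::Matrix(values, sparse = TRUE)
  if (is.null(cell_meta))
    cell_meta <- data.frame(row.names = colnames(values))
  structure(list(values = values,
                 gene_ids = rownames(values),
                 cell_ids = colnames(values),
                 norm_kind = norm_kind,
                 scale_factor = scale_factor,
                 cell_meta = cell_meta),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix (%s): %d genes x %d cells\n",
              x$norm_kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' One-to-one orthologue map between two species
#'
#' @param pairs two-column data.frame of paired gene ids (column 1: species A,
#'   column 2: species B). Each gene may appear in at most one pair.
#' @param specific_a,specific_b character vectors of genes with no partner
#'   in the other species.
#' @return An object of class `orthologue_map`.
#' @export
orthologue_map <- function(pairs, specific_a = character(),
                           specific_b = character()) {
  pairs <- as.data.frame(pairs)
  stopifnot(ncol(pairs) == 2)
  colnames(pairs) <- c("gene_a", "gene_b")
  if (anyDuplicated(pairs$gene_a) || anyDuplicated(pairs$gene_b))
    stop("orthologue pairing must be one-to-one")
  if (length(intersect(pairs$gene_a, specific_a)) ||
      length(intersect(pairs$gene_b, specific_b)))
    stop("species-specific genes cannot also be paired")
  structure(list(pairs = pairs,
                 specific_a = specific_a, specific_b = specific_b),
            class = "orthologue_map")
}

#' @export
print.orthologue_map <- function(x, ...) {
  cat(sprintf("orthologue_map: %d one-to-one pairs; %d / %d species-specific\n",
              nrow(x$pairs), length(x$specific_a), length(x$specific_b)))
  invisible(x)
}
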