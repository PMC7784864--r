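#' Read a 10x Genomics triplet directory
#'
#' Reads `matrix.mtx` (or `matrix.mtx.gz`), `genes.tsv` / `features.tsv` and
#' `barcodes.tsv` from a directory into a [count_matrix()]. MatrixMarket
#' coordinates are 1-based per the format definition. A `cell_meta.tsv`
#' written by [write_10x()] is restored when present. Duplicate gene
#' identifiers are made unique by suffixing (with a message).
#'
#' @param dir_path directory holding the triplet files.
#' @return A [count_matrix()].
#' @export
read_10x <- function(dir_path) {
  find1 <- function(cands) {
    for (f in cands) {
      p <- file.path(dir_path, f)
      if (file.exists(p)) return(p)
    }
    stop("missing file in ", dir_path, ": tried ",
         paste(cands, collapse = ", "))
  }
  mtx <- find1(c("matrix.mtx", "matrix.mtx.gz"))
  genes_f <- find1(c("genes.tsv", "genes.tsv.gz",
                     "features.tsv", "features.tsv.gz"))
  bc_f <- find1(c("barcodes.tsv", "barcodes.tsv.gz"))
  counts <- as(Matrix::readMM(mtx), "CsparseMatrix")
  genes <- read.delim(genes_f, header = FALSE, stringsAsFactors = FALSE)
  barcodes <- read.delim(bc_f, header = FALSE, stringsAsFactors = FALSE)[, 1]
  if (nrow(genes) != nrow(counts))
    stop(sprintf("dimension mismatch: MTX header has %d genes but %s has %d",
                 nrow(counts), basename(genes_f), nrow(genes)))
  if (length(barcodes) != ncol(counts))
    stop(sprintf("dimension mismatch: MTX header has %d cells but %s has %d",
                 ncol(counts), basename(bc_f), length(barcodes)))
  gene_ids <- genes[, 1]
  if (anyDuplicated(gene_ids)) {
    message("duplicate gene identifiers made unique by suffixing")
    gene_ids <- make.unique(gene_ids)
  }
  dimnames(counts) <- list(gene_ids, barcodes)
  meta_f <- file.path(dir_path, "cell_meta.tsv")
  meta <- if (file.exists(meta_f)) {
    read.delim(meta_f, row.names = 1, stringsAsFactors = FALSE)
  } else NULL
  count_matrix(counts, meta)
}

#' Write a count matrix as a 10x Genomics triplet directory
#'
#' Writes `matrix.mtx` (MatrixMarket coordinate integer), a two-column
#' `genes.tsv` (id, symbol), `barcodes.tsv`, and the cell metadata as
#' `cell_meta.tsv` so that [read_10x()] round-trips exactly.
#'
#' @param m a [count_matrix()].
#' @param dir_path output directory (created if needed).
#' @return `dir_path`, invisibly.
#' @export
write_10x <- function(m, dir_path) {
  stopifnot(inherits(m, "count_matrix"))
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(m$counts, file.path(dir_path, "matrix.mtx"))
  write.table(data.frame(m$gene_ids, m$gene_ids),
              file.path(dir_path, "genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(data.frame(m$cell_ids), file.path(dir_path, "barcodes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (ncol(m$cell_meta))
    write.table(m$cell_meta, file.path(dir_path, "cell_meta.tsv"),
                sep = "\t", quote = FALSE, row.names = TRUE, col.names = NA)
  invisible(dir_path)
}

#' Read / write a dense TSV count matrix
#'
#' Plain-text alternative to the triplet format: genes in rows, cells in
#' columns, first column holding gene ids.
#'
#' @param path TSV file path.
#' @return [read_dense_tsv()]: a [count_matrix()].
#' @export
read_dense_tsv <- function(path) {
  df <- read.delim(path, row.names = 1, check.names = FALSE)
  count_matrix(as.matrix(df))
}

#' @rdname read_dense_tsv
#' @param m a [count_matrix()].
#' @export
write_dense_tsv <- function(m, path) {
  write.table(as.matrix(m$counts), path, sep = "\t", quote = FALSE,
              row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Read a two-column orthologue table
#'
#' @param path TSV with two columns of paired gene ids (no header).
#' @param specific_a,specific_b optional species-specific gene sets.
#' @return An [orthologue_map()].
#' @export
read_orthologues <- function(path, specific_a = character(),
                             specific_b = character()) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  orthologue_map(df[, 1:2], specific_a, specific_b)
}
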