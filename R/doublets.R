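#' Parameters for artificial-doublet detection
#'
#' @param sample_fraction fraction of cells sampled (twice) to build
#'   artificial doublets; the default 0.10 yields `round(0.1 * N)` artificial
#'   cells.
#' @param neighborhood_fraction neighbourhood size as a fraction of the
#'   union (real + artificial) dataset; the doublet index of a cell is the
#'   proportion of artificial doublets among its
#'   `k = max(1, round(neighborhood_fraction * N_union))` nearest neighbours
#'   in PC space.
#' @param putative_quantile cells with doublet indices at or above this
#'   empirical quantile are flagged putative (0.90 flags the top 10%).
#' @param n_pcs number of principal components for the joint embedding.
#' @param definitive_cluster_fraction clusters whose putative-doublet
#'   fraction exceeds this value are called definitive doublets.
#' @param resolution Louvain resolution used when re-clustering on
#'   doublet-related genes.
#' @param seed integer seed.
#' @return A list of class `doublet_params`.
#' @export
doublet_params <- function(sample_fraction = 0.10,
                           neighborhood_fraction = 0.01,
                           putative_quantile = 0.90,
                           n_pcs = 20,
                           definitive_cluster_fraction = 0.5,
                           resolution = 0.8,
                           seed = 1) {
  stopifnot(sample_fraction > 0, sample_fraction < 1,
            neighborhood_fraction > 0, neighborhood_fraction < 1,
            putative_quantile > 0, putative_quantile < 1, n_pcs >= 2)
  structure(as.list(environment()), class = "doublet_params")
}

#' Build artificial doublets by merging random cell pairs
#'
#' Samples `round(sample_fraction * N)` cells twice, without replacement
#' within each subset, and merges the two subsets pairwise by summing their
#' count vectors. Pairings of a cell with itself are re-drawn.
#'
#' @param m a [count_matrix()].
#' @param p a [doublet_params()].
#' @return A [count_matrix()] of the artificial cells only; its `cell_meta`
#'   records the two parent cell ids.
#' @export
make_artificial_doublets <- function(m, p = doublet_params()) {
  stopifnot(inherits(m, "count_matrix"))
  n <- ncol(m$counts)
  if (n < 20) stop("need at least 20 cells to simulate doublets")
  n_art <- round(p$sample_fraction * n)
  if (n_art < 1) stop("sample_fraction * N < 1: no artificial doublets")
  withr::with_seed(p$seed, {
    s1 <- sample.int(n, n_art)
    s2 <- sample.int(n, n_art)
    while (any(s1 == s2)) {
      hit <- which(s1 == s2)
      s2[hit] <- sample.int(n, length(hit), replace = TRUE)
    }
  })
  art <- m$counts[, s1, drop = FALSE] + m$counts[, s2, drop = FALSE]
  colnames(art) <- sprintf("art%05d", seq_len(n_art))
  meta <- data.frame(parent_1 = m$cell_ids[s1], parent_2 = m$cell_ids[s2],
                     row.names = colnames(art), stringsAsFactors = FALSE)
  count_matrix(art, meta)
}

#' Doublet index from a joint embedding
#'
#' For each real cell, finds its `k = max(1, round(neighborhood_fraction *
#' N_union))` nearest neighbours (Euclidean distance in the joint PC space,
#' self excluded) and returns the proportion of artificial doublets among
#' them.
#'
#' @param coords union (real + artificial) cells x PCs coordinate matrix.
#' @param is_artificial logical vector marking the artificial rows.
#' @param neighborhood_fraction neighbourhood size as a fraction of the
#'   union.
#' @return Named numeric vector of doublet indices in \[0, 1\], one per real
#'   cell.
#' @export
doublet_knn_index <- function(coords, is_artificial,
                              neighborhood_fraction = 0.01) {
  coords <- as.matrix(coords)
  n_union <- nrow(coords)
  stopifnot(length(is_artificial) == n_union)
  k <- max(1L, round(neighborhood_fraction * n_union))
  if (k >= n_union) stop("neighbourhood size k must be < N_union")
  nn <- knn_indices(coords, k)
  idx <- rowMeans(matrix(is_artificial[nn], nrow = n_union))
  setNames(idx[!is_artificial],
           rownames(coords)[!is_artificial])
}

#' Flag putative doublets from doublet indices
#'
#' Flags every cell whose index is at or above the `putative_quantile`
#' empirical order statistic. With distinct indices this flags exactly the
#' top `1 - putative_quantile` fraction; under ties the flagged set can be
#' larger (the tie rule is inclusive), and a fully tied vector flags all
#' cells with a message.
#'
#' @param indices numeric doublet indices.
#' @param p a [doublet_params()].
#' @return Logical vector of putative flags.
#' @export
call_putative <- function(indices, p = doublet_params()) {
  n <- length(indices)
  stopifnot(n >= 10)
  n_top <- max(1L, round((1 - p$putative_quantile) * n))
  thr <- sort(indices, decreasing = TRUE)[n_top]
  flags <- indices >= thr
  if (all(flags)) message("degenerate doublet indices: all cells tied")
  flags
}

#' Call definitive doublets by re-clustering on doublet-related genes
#'
#' Performs Wilcoxon rank-sum differential expression between putative
#' doublets and the remaining cells (Bonferroni-adjusted p < 0.01 and
#' |ln-FC| > 0.25 define doublet-related genes), re-embeds and clusters the
#' cells on those genes, and flags every member of clusters whose
#' putative-doublet fraction exceeds `definitive_cluster_fraction`.
#'
#' @param nm a [normalized_matrix()] of the real cells.
#' @param putative logical putative flags, one per cell of `nm`.
#' @param p a [doublet_params()].
#' @return A list of class `doublet_call` with `doublet_genes`, `definitive`
#'   flags, `cluster_labels` and `cluster_putative_fraction`.
#' @export
definitive_doublets <- function(nm, putative, p = doublet_params()) {
  stopifnot(inherits(nm, "normalized_matrix"),
            length(putative) == ncol(nm$values))
  if (!any(putative) || all(putative))
    stop("both putative and non-putative cells are required")
  de <- wilcoxon_de(nm, which(putative), which(!putative))
  p_adj <- pmin(de$p_value * length(de$p_value), 1)
  genes <- nm$gene_ids[p_adj < 0.01 & abs(de$log_fc) > 0.25]
  if (length(genes) < 2) {
    warning("no doublet-related genes found; empty definitive set")
    return(structure(list(doublet_genes = character(),
                          definitive = rep(FALSE, length(putative)),
                          cluster_labels = rep("1", length(putative)),
                          cluster_putative_fraction = c(`1` = mean(putative))),
                     class = "doublet_call"))
  }
  emb <- run_pca(nm$values, genes = genes,
                 n_pcs = min(10, length(genes) - 1))
  labels <- cluster_embedding(emb$scores, k_neighbors = 20,
                              resolution = p$resolution, seed = p$seed)
  frac <- tapply(putative, labels, mean)
  hot <- names(frac)[frac > p$definitive_cluster_fraction]
  structure(list(doublet_genes = genes,
                 definitive = labels %in% hot,
                 cluster_labels = labels,
                 cluster_putative_fraction = frac),
            class = "doublet_call")
}

#' Full two-stage doublet detection
#'
#' Runs the complete pipeline: artificial doublets are simulated by merging
#' random cell pairs, the union of real and artificial cells is normalized
#' and embedded by PCA on its variable genes, each real cell's doublet index
#' is the proportion of artificial doublets among its nearest neighbours,
#' the top `1 - putative_quantile` of indices become putative doublets, and
#' re-clustering on doublet-related genes upgrades whole clusters with a
#' high putative fraction to definitive doublets.
#'
#' @param m a [count_matrix()] of real cells.
#' @param p a [doublet_params()].
#' @param call_definitive if `FALSE`, stop after the putative stage.
#' @return A list of class `doublet_call` with `doublet_index`, `putative`,
#'   `definitive`, `doublet_genes`, `cluster_putative_fraction`,
#'   `n_artificial`, and `params`.
#' @export
detect_doublets <- function(m, p = doublet_params(), call_definitive = TRUE) {
  stopifnot(inherits(m, "count_matrix"))
  art <- make_artificial_doublets(m, p)
  union_counts <- cbind(m$counts, art$counts)
  union_m <- count_matrix(union_counts)
  nm_union <- normalize_log(union_m)
  vg <- find_variable_genes(nm_union)
  genes <- if (length(vg$gene_ids) >= p$n_pcs + 1) vg$gene_ids else
    names(sort(vg$dispersion_z, decreasing = TRUE))[seq_len(
      min(500, nrow(union_counts)))]
  emb <- run_pca(nm_union$values, genes = genes, n_pcs = p$n_pcs)
  is_art <- c(rep(FALSE, ncol(m$counts)), rep(TRUE, ncol(art$counts)))
  idx <- doublet_knn_index(emb$scores, is_art, p$neighborhood_fraction)
  put <- call_putative(idx, p)
  res <- list(doublet_index = idx, putative = put,
              definitive = rep(FALSE, length(put)),
              doublet_genes = character(),
              cluster_putative_fraction = numeric(),
              n_artificial = ncol(art$counts), params = p)
  if (call_definitive && any(put) && !all(put)) {
    nm_real <- normalize_log(m)
    def <- definitive_doublets(nm_real, put, p)
    res$definitive <- def$definitive
    res$doublet_genes <- def$doublet_genes
    res$cluster_putative_fraction <- def$cluster_putative_fraction
  }
  structure(res, class = "doublet_call")
}

#' @export
print.doublet_call <- function(x, ...) {
  cat(sprintf("doublet_call: %d cells, %d putative, %d definitive\n",
              length(x$putative), sum(x$putative), sum(x$definitive)))
  invisible(x)
}

#' Remove erythrocyte-derived doublets via hemoglobin-gene clustering
#'
#' Identifies the principal component with the largest aggregate hemoglobin
#' gene loading, takes the genes with the top absolute loadings on that
#' component as the clustering space, clusters the cells on those genes, and
#' removes clusters with high hemoglobin expression. Removal only happens
#' when the per-cluster mean hemoglobin scores actually separate (range
#' above `sep_threshold`); uniform hemoglobin expression removes nothing.
#'
#' @param m a [count_matrix()].
#' @param hb_gene_ids hemoglobin gene ids (must be present in `m`).
#' @param n_top_genes number of top-loading genes defining the clustering
#'   space.
#' @param sep_threshold minimal range (ln scale) of per-cluster mean
#'   hemoglobin scores required before any cluster is removed.
#' @param seed integer seed.
#' @return A list with the filtered [count_matrix()] (`matrix`), the removed
#'   cell ids (`removed`), the selected PC (`pc`), and the clustering genes.
#' @export
hemoglobin_doublet_removal <- function(m, hb_gene_ids, n_top_genes = 30,
                                       sep_threshold = 1, seed = 1) {
  stopifnot(inherits(m, "count_matrix"))
  if (!all(hb_gene_ids %in% m$gene_ids))
    stop("hemoglobin genes absent from matrix: ",
         paste(setdiff(hb_gene_ids, m$gene_ids), collapse = ", "))
  nm <- normalize_log(m)
  hb_expr <- Matrix::colMeans(nm$values[hb_gene_ids, , drop = FALSE])
  if (all(hb_expr == 0))
    return(list(matrix = m, removed = character(), pc = NA_integer_,
                genes = character()))
  vg <- find_variable_genes(nm)
  genes <- union(vg$gene_ids, hb_gene_ids)
  emb <- run_pca(nm$values, genes = genes, n_pcs = min(10, length(genes) - 1))
  hb_load <- colSums(emb$loadings[hb_gene_ids, , drop = FALSE]^2)
  pc <- which.max(hb_load)
  load_pc <- abs(emb$loadings[, pc])
  space <- names(sort(load_pc, decreasing = TRUE))[
    seq_len(min(n_top_genes, length(load_pc)))]
  emb2 <- run_pca(nm$values, genes = space,
                  n_pcs = min(5, length(space) - 1))
  labels <- cluster_embedding(emb2$scores, k_neighbors = 20,
                              resolution = 0.8, seed = seed)
  score <- tapply(hb_expr, labels, mean)
  removed <- character()
  if (length(score) > 1 && (max(score) - min(score)) > sep_threshold) {
    hot <- names(score)[score > (max(score) + min(score)) / 2]
    removed <- m$cell_ids[labels %in% hot]
  }
  keep <- setdiff(m$cell_ids, removed)
  list(matrix = subset_cells(m, cells = keep), removed = removed,
       pc = pc, genes = space)
}
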