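# Shared-nearest-neighbour weights from kNN sets (self included): Jaccard
# overlap of the two cells' neighbour sets; edges below `prune` are dropped.
snn_graph <- function(coords, k_neighbors = 30, prune = 1 / 15) {
  n <- nrow(coords)
  k <- min(k_neighbors, n - 1)
  nn <- knn_indices(coords, k)
  sets <- cbind(seq_len(n), nn)          # neighbour sets of size k + 1
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), ncol(sets)),
                              j = as.vector(sets), x = 1,
                              dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  ksz <- ncol(sets)
  snn <- shared
  snn@x <- snn@x / (2 * ksz - snn@x)     # Jaccard: |A^B| / |AvB|
  snn@x[snn@x < prune] <- 0
  snn <- Matrix::drop0(snn)
  diag(snn) <- 0
  Matrix::drop0(snn)
}

#' Cluster cells from an embedding via SNN + Louvain
#'
#' Builds a k-nearest-neighbour graph in the given coordinate space,
#' re-weights edges by the Jaccard overlap of neighbour sets (shared nearest
#' neighbours), and partitions the graph with Louvain modularity
#' optimization.
#'
#' @param coords cells x dimensions coordinate matrix.
#' @param k_neighbors neighbours per cell for the kNN graph.
#' @param resolution Louvain resolution.
#' @param seed integer seed (Louvain is stochastic).
#' @param prune SNN edges below this Jaccard weight are dropped.
#' @return Character vector of cluster labels ("1", "2", ...), one per cell.
#' @export
cluster_embedding <- function(coords, k_neighbors = 30, resolution = 0.8,
                              seed = 1, prune = 1 / 15) {
  snn <- snn_graph(coords, k_neighbors, prune)
  g <- igraph::graph_from_adjacency_matrix(snn, mode = "undirected",
                                           weighted = TRUE)
  comm <- withr::with_seed(seed,
    igraph::cluster_louvain(g, resolution = resolution))
  as.character(igraph::membership(comm))
}

#' Merge clusters without marker support
#'
#' Modularity optimization finds communities even in structureless data, so
#' clusters are only kept apart when some gene separates them: any pair of
#' clusters whose strongest gene-level contrast (natural-log fold change of
#' back-transformed cluster means) stays below `min_sep_log_fc` is merged,
#' iteratively, starting from the least-separated pair.
#'
#' @param nm a [normalized_matrix()].
#' @param labels cluster label per cell.
#' @param min_sep_log_fc minimal max-gene |ln-FC| for two clusters to stay
#'   separate.
#' @return Character label vector with unsupported clusters merged.
#' @export
merge_markerless_clusters <- function(nm, labels, min_sep_log_fc = 1) {
  labels <- as.character(labels)
  v <- expm1(as.matrix(nm$values))
  repeat {
    cl <- sort(unique(labels))
    if (length(cl) < 2) break
    means <- vapply(cl, function(g)
      rowMeans(v[, labels == g, drop = FALSE]), numeric(nrow(v)))
    lm <- log1p(means)
    sep <- matrix(Inf, length(cl), length(cl))
    for (i in seq_along(cl)) for (j in seq_len(i - 1))
      sep[i, j] <- max(abs(lm[, i] - lm[, j]))
    min_pair <- which(sep == min(sep), arr.ind = TRUE)[1, ]
    if (sep[min_pair[1], min_pair[2]] >= min_sep_log_fc) break
    labels[labels == cl[min_pair[1]]] <- cl[min_pair[2]]
  }
  labels
}

#' SNN graph clustering of a normalized matrix
#'
#' The standard single-round clustering pipeline: variable genes, scaled
#' PCA, SNN graph, Louvain communities, then a marker-support check that
#' merges cluster pairs no gene separates (see
#' [merge_markerless_clusters()]).
#'
#' @param nm a [normalized_matrix()].
#' @param n_pcs principal components to use.
#' @param k_neighbors neighbours for the SNN graph.
#' @param resolution Louvain resolution.
#' @param seed integer seed.
#' @param genes optional gene set overriding variable-gene selection.
#' @param min_sep_log_fc marker-support threshold for
#'   [merge_markerless_clusters()]; 0 disables merging.
#' @return A list of class `cluster_result`: `labels`, `embedding`
#'   (the PCA object from the internal run), `resolution`, `graph_k`.
#' @export
snn_cluster <- function(nm, n_pcs = 20, k_neighbors = 30, resolution = 0.8,
                        seed = 1, genes = NULL, min_sep_log_fc = 1) {
  stopifnot(inherits(nm, "normalized_matrix"))
  if (is.null(genes)) {
    vg <- find_variable_genes(nm)
    genes <- vg$gene_ids
    if (length(genes) < n_pcs + 1)
      genes <- names(sort(vg$dispersion_z, decreasing = TRUE))[
        seq_len(min(500, nrow(nm$values)))]
  }
  emb <- run_pca(nm$values, genes = genes,
                 n_pcs = min(n_pcs, length(genes) - 1))
  labels <- cluster_embedding(emb$scores, k_neighbors, resolution, seed)
  if (min_sep_log_fc > 0)
    labels <- merge_markerless_clusters(nm, labels, min_sep_log_fc)
  labels <- as.character(as.integer(factor(labels)))
  structure(list(labels = setNames(labels, nm$cell_ids), embedding = emb,
                 resolution = resolution, graph_k = k_neighbors),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d cells in %d clusters\n",
              length(x$labels), length(unique(x$labels))))
  invisible(x)
}

#' Second-round clustering within major populations
#'
#' Isolates each requested major population and re-runs the full pipeline
#' (normalization, variable genes, PCA, SNN + Louvain) inside it. Sub-labels
#' are namespaced as `"<major>.<sub>"`; cells of unlisted majors keep their
#' major label.
#'
#' @param m a [count_matrix()].
#' @param major_labels vector of first-round labels, one per cell.
#' @param subsets major labels to subcluster (default: all).
#' @param ... passed to [snn_cluster()].
#' @return A `cluster_result` with nested labels and per-cell `round` depth.
#' @export
iterative_subcluster <- function(m, major_labels, subsets = NULL, ...) {
  stopifnot(inherits(m, "count_matrix"),
            length(major_labels) == ncol(m$counts))
  if (is.null(subsets)) subsets <- unique(major_labels)
  labels <- as.character(major_labels)
  round_depth <- rep(1L, length(labels))
  for (maj in subsets) {
    idx <- which(major_labels == maj)
    if (length(idx) < 25) next
    sub_m <- subset_cells(m, cells = idx)
    keep_genes <- Matrix::rowSums(sub_m$counts) > 0
    sub_m <- subset_cells(sub_m, genes = which(keep_genes))
    sub <- snn_cluster(normalize_log(sub_m), ...)
    labels[idx] <- paste0(maj, ".", sub$labels)
    round_depth[idx] <- 2L
  }
  structure(list(labels = setNames(labels, m$cell_ids), round = round_depth),
            class = "cluster_result")
}

#' Center an embedding per batch
#'
#' Simple linear batch correction in a reduced space: subtracts each batch's
#' mean coordinate and restores the global mean, so batches share a common
#' centroid while within-batch structure is untouched.
#'
#' @param embedding cells x dimensions matrix.
#' @param batch batch label per cell.
#' @return The corrected embedding.
#' @export
batch_center <- function(embedding, batch) {
  embedding <- as.matrix(embedding)
  stopifnot(length(batch) == nrow(embedding))
  if (length(unique(batch)) < 2) return(embedding)
  global <- colMeans(embedding)
  out <- embedding
  for (b in unique(batch)) {
    idx <- batch == b
    shift <- colMeans(embedding[idx, , drop = FALSE]) - global
    out[idx, ] <- sweep(embedding[idx, , drop = FALSE], 2, shift)
  }
  out
}

#' Annotate clusters from a marker panel
#'
#' Scores each cluster for each cell type as the mean (across the type's
#' marker genes) of the cluster-mean expression, z-scored per gene across
#' clusters so types with different baseline marker expression are
#' comparable. Each cluster is assigned the arg-max type; exact ties yield
#' `"unassigned"` with a warning. Panel genes missing from the matrix are
#' skipped with a message.
#'
#' @param nm a [normalized_matrix()].
#' @param labels cluster label per cell.
#' @param marker_panel data.frame with columns `type` and `gene_id`.
#' @return Named character vector: type per cluster.
#' @export
annotate_clusters <- function(nm, labels, marker_panel) {
  stopifnot(inherits(nm, "normalized_matrix"),
            length(labels) == ncol(nm$values),
            all(c("type", "gene_id") %in% colnames(marker_panel)))
  missing <- setdiff(marker_panel$gene_id, nm$gene_ids)
  if (length(missing)) {
    message("skipping ", length(missing), " panel genes absent from matrix")
    marker_panel <- marker_panel[marker_panel$gene_id %in% nm$gene_ids, ]
  }
  if (!nrow(marker_panel)) stop("no panel genes present in matrix")
  cl <- sort(unique(as.character(labels)))
  panel_genes <- unique(marker_panel$gene_id)
  mean_expr <- vapply(cl, function(g)
    Matrix::rowMeans(nm$values[panel_genes, labels == g, drop = FALSE]),
    numeric(length(panel_genes)))
  mean_expr <- matrix(mean_expr, nrow = length(panel_genes),
                      dimnames = list(panel_genes, cl))
  if (length(cl) > 1) {
    mu <- rowMeans(mean_expr)
    s <- apply(mean_expr, 1, sd)
    mean_expr <- (mean_expr - mu) / ifelse(s == 0, 1, s)
  }
  types <- unique(marker_panel$type)
  scores <- vapply(types, function(ty) {
    g <- marker_panel$gene_id[marker_panel$type == ty]
    colMeans(mean_expr[g, , drop = FALSE])
  }, numeric(length(cl)))
  scores <- matrix(scores, nrow = length(cl),
                   dimnames = list(cl, types))
  assign1 <- function(row) {
    top <- max(row)
    winners <- names(row)[row >= top - 1e-12]
    if (length(winners) > 1) "unassigned" else winners
  }
  out <- apply(scores, 1, assign1)
  if (any(out == "unassigned"))
    warning("tied marker scores: some clusters left unassigned")
  out
}

#' Cross-species cell-type correlation over orthologues
#'
#' Computes mean normalized expression per cell type in each species over
#' the one-to-one orthologous genes and returns the all-pairs Pearson
#' correlation between type profiles, both across species (`corr`) and over
#' the joint set of both species' types (`corr_all`, used for family
#' grouping).
#'
#' By default each gene's profile is standardized across types within its
#' species before correlating, so the correlation reflects relative
#' expression patterns rather than shared baseline expression levels (the
#' baseline is nearly identical for every pair of types and would otherwise
#' dominate the correlation).
#'
#' @param nm_a,nm_b [normalized_matrix()] objects for species A and B.
#' @param types_a,types_b cell-type label per cell.
#' @param ortho an [orthologue_map()].
#' @param genes optional restriction to informative genes (ids in the
#'   species-A namespace), e.g. the union of differentially expressed genes.
#' @param standardize z-score each gene across types within species before
#'   correlating.
#' @return A list of class `type_correlation` with `mean_expr_a`,
#'   `mean_expr_b` (types x orthologues), `corr` (types A x types B),
#'   `corr_all` (joint square matrix; rownames prefixed `A:` / `B:`).
#' @export
crossspecies_type_correlation <- function(nm_a, nm_b, types_a, types_b,
                                          ortho, genes = NULL,
                                          standardize = TRUE) {
  stopifnot(inherits(ortho, "orthologue_map"))
  pairs <- ortho$pairs
  pairs <- pairs[pairs$gene_a %in% nm_a$gene_ids &
                 pairs$gene_b %in% nm_b$gene_ids, ]
  if (!is.null(genes)) pairs <- pairs[pairs$gene_a %in% genes, ]
  if (nrow(pairs) < 3) stop("need at least 3 shared orthologues")
  type_means <- function(nm, sel, types) {
    lv <- sort(unique(as.character(types)))
    mm <- vapply(lv, function(ty)
      Matrix::rowMeans(nm$values[sel, types == ty, drop = FALSE]),
      numeric(length(sel)))
    t(matrix(mm, nrow = length(sel), dimnames = list(sel, lv)))
  }
  ma <- type_means(nm_a, pairs$gene_a, types_a)
  mb <- type_means(nm_b, pairs$gene_b, types_b)
  if (standardize) {
    std <- function(m) {
      s <- apply(m, 2, sd)
      sweep(sweep(m, 2, colMeans(m)), 2, ifelse(s == 0, 1, s), "/")
    }
    ma <- std(ma)
    mb <- std(mb)
  }
  corr <- cor(t(ma), t(mb))
  joint <- rbind(ma, mb)
  rownames(joint) <- c(paste0("A:", rownames(ma)), paste0("B:", rownames(mb)))
  structure(list(mean_expr_a = ma, mean_expr_b = mb, corr = corr,
                 corr_all = cor(t(joint))),
            class = "type_correlation")
}

#' Group cell types into lineage families
#'
#' Average-linkage hierarchical clustering of cell types (both species
#' jointly) on the distance `1 - correlation`, cut into `n_families` groups.
#'
#' @param tc a `type_correlation` from [crossspecies_type_correlation()], or
#'   a square correlation matrix.
#' @param n_families number of families to cut.
#' @return Named character vector: family id ("1"..) per type profile.
#' @export
family_grouping <- function(tc, n_families = 4) {
  corr <- if (inherits(tc, "type_correlation")) tc$corr_all else as.matrix(tc)
  stopifnot(nrow(corr) == ncol(corr), n_families <= nrow(corr))
  hc <- hclust(as.dist(1 - corr), method = "average")
  setNames(as.character(cutree(hc, k = n_families)), rownames(corr))
}
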