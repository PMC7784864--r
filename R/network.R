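#' Build a weighted gene co-expression network with topological overlap
#'
#' Unsigned weighted network over a gene set: adjacency
#' `a_ij = |cor(x_i, x_j)|^beta`, topological overlap
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k_i = sum_{u != i} a_iu` (TOM diagonal set to 1 by convention), module
#' detection by average-linkage hierarchical clustering on `1 - TOM` with a
#' static height cut (modules smaller than `min_module_size` become
#' unassigned, module "0"), and per-gene centrality defined as the weighted
#' degree `k_i`.
#'
#' With a soft power of 6, absolute TOM values depend strongly on the
#' overall correlation level of the data, so the default cut height is
#' data-driven: the `cut_quantile` quantile of the dendrogram's own merge
#' heights, which separates the few high inter-module merges from the bulk
#' of within-module merges regardless of the absolute TOM scale. Pass an
#' explicit `cut_height` to override.
#'
#' @param nm a [normalized_matrix()] (or genes x cells matrix).
#' @param genes gene ids to include (>= 3).
#' @param beta soft-thresholding power (unsigned convention).
#' @param cut_height static cut height on the `1 - TOM` dendrogram; `NULL`
#'   (default) uses the merge-height quantile rule.
#' @param cut_quantile merge-height quantile defining the default cut.
#' @param min_module_size modules below this size are unassigned.
#' @return A list of class `gene_network`: `genes`, `adjacency`, `beta`,
#'   `tom`, `modules` (named character; "0" = unassigned), `centrality`.
#' @export
build_network <- function(nm, genes = NULL, beta = 6, cut_height = NULL,
                          cut_quantile = 0.95, min_module_size = 10) {
  v <- if (inherits(nm, "normalized_matrix")) as.matrix(nm$values) else
    as.matrix(nm)
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  stopifnot(nrow(v) >= 3, ncol(v) >= 3)
  r <- cor(t(v))
  r[is.na(r)] <- 0
  adj <- abs(r)^beta
  diag(adj) <- 0
  tom <- tom_from_adjacency(adj)
  k <- rowSums(adj)
  hc <- hclust(as.dist(1 - tom), method = "average")
  if (is.null(cut_height))
    cut_height <- unname(quantile(hc$height, cut_quantile))
  modules <- as.character(cutree(hc, h = cut_height))
  tab <- table(modules)
  small <- names(tab)[tab < min_module_size]
  modules[modules %in% small] <- "0"
  structure(list(genes = rownames(v), adjacency = adj, beta = beta,
                 tom = tom, modules = setNames(modules, rownames(v)),
                 centrality = setNames(k, rownames(v)),
                 dendrogram = hc),
            class = "gene_network")
}

# Topological overlap from an adjacency matrix with zero diagonal.
tom_from_adjacency <- function(adj) {
  stopifnot(isSymmetric(unname(adj)), all(diag(adj) == 0))
  k <- rowSums(adj)
  num <- adj %*% adj + adj
  den <- outer(k, k, pmin) + 1 - adj
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' @export
print.gene_network <- function(x, ...) {
  n_mod <- length(setdiff(unique(x$modules), "0"))
  cat(sprintf("gene_network: %d genes, beta = %g, %d modules\n",
              length(x$genes), x$beta, n_mod))
  invisible(x)
}

#' Cross-species network structure similarity
#'
#' Pearson correlation between per-gene centralities (weighted degree) of
#' two co-expression networks over the orthologue-paired shared genes.
#'
#' @param net_a,net_b `gene_network` objects.
#' @param ortho an [orthologue_map()]; defaults to pairing identical ids.
#' @return A list with `r` (the Pearson correlation), `n_shared`, and the
#'   paired centralities.
#' @export
centrality_correlation <- function(net_a, net_b, ortho = NULL) {
  if (is.null(ortho)) {
    shared <- intersect(net_a$genes, net_b$genes)
    pairs <- data.frame(gene_a = shared, gene_b = shared)
  } else {
    pairs <- ortho$pairs
  }
  pairs <- pairs[pairs$gene_a %in% net_a$genes &
                 pairs$gene_b %in% net_b$genes, ]
  if (nrow(pairs) < 3) stop("need at least 3 shared genes")
  ca <- net_a$centrality[pairs$gene_a]
  cb <- net_b$centrality[pairs$gene_b]
  list(r = cor(ca, cb), n_shared = nrow(pairs),
       centrality_a = ca, centrality_b = cb)
}

#' Eigengene of a gene set
#'
#' First principal component of the per-gene standardized expression of a
#' gene set, summarizing the set's activity per cell. The eigengene is
#' scaled to unit variance and sign-oriented to correlate positively with
#' the set's mean scaled expression.
#'
#' @param nm a [normalized_matrix()] (or genes x cells matrix).
#' @param gene_set gene ids (>= 2) present in the matrix.
#' @return A list of class `eigengene_profile`: `eigengene` (per-cell,
#'   unit variance), `gene_correlations` (per-gene Pearson r to the
#'   eigengene), `var_explained`.
#' @export
eigengene <- function(nm, gene_set) {
  v <- if (inherits(nm, "normalized_matrix")) as.matrix(nm$values) else
    as.matrix(nm)
  gene_set <- intersect(gene_set, rownames(v))
  stopifnot(length(gene_set) >= 2)
  z <- scale_genes(v[gene_set, , drop = FALSE])
  pc <- prcomp(t(z), center = FALSE, scale. = FALSE, rank. = 1)
  eg <- pc$x[, 1]
  if (sd(eg) == 0) stop("degenerate gene set: eigengene has zero variance")
  eg <- eg / sd(eg)
  ref <- colMeans(z)
  if (cor(eg, ref) < 0) eg <- -eg
  gc <- apply(v, 1, function(x) if (sd(x) == 0) 0 else cor(x, eg))
  structure(list(eigengene = setNames(eg, colnames(v)),
                 gene_correlations = setNames(gc, rownames(v)),
                 var_explained = pc$sdev[1]^2 / sum(apply(z, 1, var))),
            class = "eigengene_profile")
}

#' Classify species-specific expression patterns
#'
#' A gene is specific to species A when it correlates with species A's
#' eigengene (`r_a > r_threshold`) and the difference between the two
#' species' correlations exceeds `diff_threshold` (`r_a - r_b >
#' diff_threshold`); symmetrically for species B. All other genes are
#' `"shared"`.
#'
#' @param r_a,r_b per-gene Pearson correlations to the species A and B
#'   eigengenes (same length, in \[-1, 1\]).
#' @param r_threshold minimal within-species correlation (default 0.5).
#' @param diff_threshold minimal between-species correlation difference
#'   (default 0.5).
#' @return Character vector: `"specific_a"`, `"specific_b"` or `"shared"`.
#' @export
species_specific_genes <- function(r_a, r_b, r_threshold = 0.5,
                                   diff_threshold = 0.5) {
  stopifnot(length(r_a) == length(r_b),
            all(abs(r_a) <= 1 + 1e-8), all(abs(r_b) <= 1 + 1e-8))
  out <- rep("shared", length(r_a))
  out[r_a > r_threshold & (r_a - r_b) > diff_threshold] <- "specific_a"
  out[r_b > r_threshold & (r_b - r_a) > diff_threshold] <- "specific_b"
  if (!is.null(names(r_a))) names(out) <- names(r_a)
  out
}
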