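#' @importFrom Matrix Matrix colSums rowSums rowMeans colMeans t readMM writeMM
#'   sparseMatrix drop0 tcrossprod
#' @importFrom methods as is
#' @importFrom stats cor cutree dist hclust kmeans prcomp pnorm pwilcox quantile
#'   rbinom rgamma rnbinom rnorm runif sd var setNames as.dist median dnorm
#' @importFrom utils head read.delim write.table
NULL

# Derive a stream of per-operation seeds from one master seed, keeping every
# derived value a valid 32-bit integer.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
}

#' Adjusted Rand index between two labelings
#'
#' Permutation-invariant agreement between two partitions of the same cells,
#' used throughout the test suite to compare recovered clusters with planted
#' truth labels.
#'
#' @param a,b label vectors of equal length.
#' @return Scalar ARI in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# Euclidean k-nearest neighbours from a coordinate matrix (rows = points).
# Returns an n x k integer matrix of neighbour indices, self excluded,
# ordered by increasing distance.
knn_indices <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(k < n)
  sq <- rowSums(x^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  diag(d2) <- Inf
  t(apply(d2, 1, function(row) order(row)[seq_len(k)]))
}

# Internal PCA on a normalized matrix: scale the selected genes (sample SD,
# clipped), then SVD over cells. Each PC is sign-oriented so its
# largest-magnitude gene loading is positive.
run_pca <- function(values, genes = NULL, n_pcs = 20, clip = 10) {
  v <- as.matrix(values)
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  ctr <- rowMeans(v)
  scl <- apply(v, 1, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  z <- (v - ctr) / scl
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  n_pcs <- min(n_pcs, nrow(z) - 1L, ncol(z) - 1L)
  pc <- prcomp(Matrix::t(z), center = FALSE, scale. = FALSE, rank. = n_pcs)
  scores <- pc$x
  loadings <- pc$rotation
  for (j in seq_len(ncol(loadings))) {
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, loadings = loadings,
       center = ctr, scale = scl, clip = clip,
       genes = rownames(z), sdev = pc$sdev[seq_len(ncol(scores))])
}
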