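#' Parameters for balanced-resampling consensus differential expression
#'
#' @param n_per_pop cells sampled per population per repeat (default 100).
#' @param n_repeats number of sampling repeats (default 50).
#' @param p_threshold per-repeat significance threshold on the two-sided
#'   Wilcoxon p-value (default 1e-20).
#' @param impute if `TRUE`, kNN smoothing of zeros is applied to each
#'   balanced subset before testing (off by default).
#' @param impute_k neighbours used when `impute = TRUE`.
#' @param min_log_fc optional minimal ln fold change (group over rest) for a
#'   gene to be recorded in a repeat; the default `-Inf` records on the
#'   p-value alone.
#' @param seed integer seed; per-repeat seeds are derived from it.
#' @return A list of class `consensus_params`.
#' @export
consensus_params <- function(n_per_pop = 100, n_repeats = 50,
                             p_threshold = 1e-20, impute = FALSE,
                             impute_k = 10, min_log_fc = -Inf, seed = 1) {
  stopifnot(n_repeats >= 1, p_threshold > 0, p_threshold < 1, n_per_pop >= 1)
  structure(as.list(environment()), class = "consensus_params")
}

#' Sample a balanced dataset across populations
#'
#' Draws `n_per_pop` cells without replacement from each population;
#' populations smaller than the quota are taken whole with a warning.
#'
#' @param labels population label per cell.
#' @param n_per_pop cells per population.
#' @param seed integer seed.
#' @return Integer vector of selected cell indices.
#' @export
balanced_sample <- function(labels, n_per_pop = 100, seed = 1) {
  labels <- as.character(labels)
  withr::with_seed(seed, {
    idx <- lapply(sort(unique(labels)), function(pop) {
      cells <- which(labels == pop)
      if (length(cells) <= n_per_pop) {
        if (length(cells) < n_per_pop)
          warning(sprintf("population '%s' has %d < %d cells; taking all",
                          pop, length(cells), n_per_pop))
        cells
      } else sample(cells, n_per_pop)
    })
  })
  sort(unlist(idx))
}

#' k-nearest-neighbour smoothing of dropout zeros
#'
#' Contract-level dropout smoothing: for each cell, zero entries are
#' replaced by the mean of the `k` nearest cells' values for that gene;
#' non-zero entries are untouched.
#'
#' @param nm a [normalized_matrix()] or genes x cells matrix.
#' @param k number of neighbour cells.
#' @param n_pcs PCs used for the neighbour search.
#' @return A dense genes x cells matrix with zeros smoothed.
#' @export
knn_impute <- function(nm, k = 10, n_pcs = 20) {
  v <- if (inherits(nm, "normalized_matrix")) as.matrix(nm$values) else
    as.matrix(nm)
  stopifnot(k < ncol(v))
  if (all(v != 0)) return(v)
  emb <- run_pca(v, n_pcs = min(n_pcs, nrow(v) - 1, ncol(v) - 1))
  nn <- knn_indices(emb$scores, k)
  out <- v
  for (j in seq_len(ncol(v))) {
    z <- v[, j] == 0
    if (!any(z)) next
    out[z, j] <- rowMeans(v[z, nn[j, ], drop = FALSE])
  }
  out
}

# Vectorized two-sided Wilcoxon rank-sum over the rows of a dense matrix.
# `ranks` are row ranks over all cells (ties.method = "average"); `tie_term`
# is sum(t^3 - t) per row. Normal approximation with tie and continuity
# correction; exact tail via the null rank-sum distribution when both groups
# have <= 10 cells and the row has no ties.
rank_sum_p <- function(ranks, tie_term, group_cols) {
  n <- ncol(ranks)
  n1 <- length(group_cols)
  n2 <- n - n1
  W <- rowSums(ranks[, group_cols, drop = FALSE]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
  z <- W - mu
  z <- (z - sign(z) * 0.5) / sqrt(pmax(sigma2, 0))
  p <- 2 * pnorm(-abs(z))
  if (n1 <= 10 && n2 <= 10) {
    no_tie <- tie_term == 0
    if (any(no_tie)) {
      U <- W[no_tie]
      p_lo <- pwilcox(U, n1, n2)
      p_hi <- pwilcox(U - 1, n1, n2, lower.tail = FALSE)
      p[no_tie] <- pmin(2 * pmin(p_lo, p_hi), 1)
    }
  }
  p[sigma2 == 0] <- 1
  pmin(p, 1)
}

row_ranks <- function(v) {
  ranks <- t(apply(v, 1, rank, ties.method = "average"))
  tie_term <- apply(v, 1, function(x) {
    t <- rle(sort(x))$lengths
    sum(t^3 - t)
  })
  list(ranks = ranks, tie_term = tie_term)
}

#' Two-sided Wilcoxon rank-sum differential expression
#'
#' Per-gene two-sided rank-sum test of one cell group against another, with
#' tie-corrected normal approximation (continuity-corrected) and the exact
#' null distribution when both groups have at most 10 cells and no ties.
#' The fold change is the natural-log ratio of group means of
#' back-transformed values: `ln((mean(expm1 x_g) + 1)/(mean(expm1 x_r) + 1))`.
#'
#' @param nm a [normalized_matrix()] (or genes x cells matrix of ln values).
#' @param group,rest integer or logical column indices of the two groups.
#' @return data.frame with `gene_id`, `p_value`, `log_fc`.
#' @export
wilcoxon_de <- function(nm, group, rest) {
  v <- if (inherits(nm, "normalized_matrix")) as.matrix(nm$values) else
    as.matrix(nm)
  if (is.logical(group)) group <- which(group)
  if (is.logical(rest)) rest <- which(rest)
  stopifnot(length(group) >= 2, length(rest) >= 2,
            !length(intersect(group, rest)))
  sub <- v[, c(group, rest), drop = FALSE]
  rr <- row_ranks(sub)
  p <- rank_sum_p(rr$ranks, rr$tie_term, seq_along(group))
  mg <- rowMeans(expm1(v[, group, drop = FALSE]))
  mr <- rowMeans(expm1(v[, rest, drop = FALSE]))
  data.frame(gene_id = rownames(v), p_value = p,
             log_fc = log((mg + 1) / (mr + 1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Balanced-resampling consensus differential expression
#'
#' For each repeat: a balanced subset (`n_per_pop` cells per population) is
#' drawn, optionally kNN-smoothed, and every population is tested
#' one-vs-rest with the Wilcoxon rank-sum test; genes with `p <
#' p_threshold` (and `log_fc > min_log_fc`) are recorded. The consensus set
#' of a population contains exactly the genes recorded in every repeat.
#'
#' @param nm a [normalized_matrix()].
#' @param labels population label per cell.
#' @param params a [consensus_params()].
#' @return A list of class `consensus_de_result`: `per_population` (named
#'   list of consensus gene-id vectors), `n_significant` (gene x population
#'   matrix counting significant repeats), `log_fc` (gene x population mean
#'   ln-FC), `params`.
#' @export
consensus_de <- function(nm, labels, params = consensus_params()) {
  stopifnot(inherits(nm, "normalized_matrix"),
            length(labels) == ncol(nm$values))
  labels <- as.character(labels)
  pops <- sort(unique(labels))
  v_full <- as.matrix(nm$values)
  seeds <- derive_seeds(params$seed, params$n_repeats)
  n_sig <- matrix(0L, nrow(v_full), length(pops),
                  dimnames = list(rownames(v_full), pops))
  lfc_sum <- n_sig * 0
  for (r in seq_len(params$n_repeats)) {
    idx <- balanced_sample(labels, params$n_per_pop, seeds[r])
    v <- v_full[, idx, drop = FALSE]
    if (isTRUE(params$impute))
      v <- knn_impute(v, k = min(params$impute_k, ncol(v) - 1))
    lab <- labels[idx]
    rr <- row_ranks(v)
    back <- expm1(v)
    for (pop in pops) {
      cols <- which(lab == pop)
      p <- rank_sum_p(rr$ranks, rr$tie_term, cols)
      mg <- rowMeans(back[, cols, drop = FALSE])
      mr <- rowMeans(back[, -cols, drop = FALSE])
      lfc <- log((mg + 1) / (mr + 1))
      hit <- p < params$p_threshold & lfc > params$min_log_fc
      n_sig[, pop] <- n_sig[, pop] + hit
      lfc_sum[, pop] <- lfc_sum[, pop] + lfc
    }
  }
  per_pop <- lapply(pops, function(pop)
    rownames(n_sig)[n_sig[, pop] == params$n_repeats])
  names(per_pop) <- pops
  structure(list(per_population = per_pop, n_significant = n_sig,
                 log_fc = lfc_sum / params$n_repeats, params = params),
            class = "consensus_de_result")
}

#' @export
print.consensus_de_result <- function(x, ...) {
  cat(sprintf("consensus_de_result: %d populations, %s consensus genes\n",
              length(x$per_population),
              paste(lengths(x$per_population), collapse = "/")))
  invisible(x)
}
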