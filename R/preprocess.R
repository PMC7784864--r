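#' Depth-normalize and log-transform UMI counts
#'
#' Scales each cell's counts to a common total (10,000 for the droplet
#' convention, 100,000 for the deep plate convention) and applies
#' `ln(1 + x)`. The back-transform of each cell's column sums to the scale
#' factor, which the test suite checks as a conservation property.
#'
#' @param m a [count_matrix()].
#' @param scale_factor per-cell total after scaling; 1e4 gives `lnTP10K`,
#'   1e5 gives `lnTP0.1M`.
#' @return A [normalized_matrix()].
#' @export
normalize_log <- function(m, scale_factor = 1e4) {
  stopifnot(inherits(m, "count_matrix"), scale_factor > 0)
  totals <- Matrix::colSums(m$counts)
  if (any(totals == 0))
    stop("cells with zero total count: ",
         paste(head(m$cell_ids[totals == 0], 5), collapse = ", "))
  v <- m$counts
  v@x <- log1p(v@x / rep.int(totals, diff(v@p)) * scale_factor)
  kind <- if (isTRUE(all.equal(scale_factor, 1e5))) "lnTP0.1M" else "lnTP10K"
  normalized_matrix(v, kind, scale_factor, m$cell_meta)
}

#' Remove cells detecting too few genes
#'
#' Retains cells whose number of genes with count > 0 is at least
#' `min_genes`; cells strictly below the threshold are removed (matching the
#' convention that cells with fewer detected genes than the threshold fail
#' QC).
#'
#' @param m a [count_matrix()].
#' @param min_genes detected-gene threshold.
#' @return A filtered [count_matrix()]; warns if no cell survives.
#' @export
qc_min_genes <- function(m, min_genes) {
  stopifnot(inherits(m, "count_matrix"), min_genes >= 0)
  detected <- Matrix::colSums(m$counts > 0)
  keep <- detected >= min_genes
  if (!any(keep)) warning("all cells fall below the detected-gene threshold")
  subset_cells(m, cells = which(keep))
}

#' Identify highly variable genes by binned dispersion z-scores
#'
#' Mean/dispersion variable-gene selection: per gene, the mean and the
#' dispersion (variance/mean) of the back-transformed normalized values are
#' computed; dispersions are z-scored within equal-width bins of ln-scale
#' mean expression, and genes passing the z cut-off inside the mean bounds
#' are returned.
#'
#' @param nm a [normalized_matrix()].
#' @param n_bins number of equal-width mean-expression bins.
#' @param z_cutoff dispersion z-score cut-off.
#' @param mean_bounds length-2 ln-scale bounds on mean expression. The
#'   classical droplet convention is `c(0.0125, 3)` for genome-wide (~20k
#'   gene) matrices; the default upper bound here is wider because on
#'   compact gene panels per-gene means are proportionally larger and a cap
#'   of 3 would discard genuinely variable high-expression genes.
#' @return A list of class `variable_gene_set` with `gene_ids`,
#'   `dispersion_z`, `mean_bins`, `ln_mean`.
#' @export
find_variable_genes <- function(nm, n_bins = 20, z_cutoff = 1,
                                mean_bounds = c(0.0125, 8)) {
  stopifnot(inherits(nm, "normalized_matrix"), ncol(nm$values) >= 2)
  back <- expm1(as.matrix(nm$values))
  mu <- rowMeans(back)
  vr <- apply(back, 1, var)
  disp <- ifelse(mu > 0, vr / mu, 0)
  ln_mean <- log1p(mu)
  if (all(disp == 0)) {
    warning("degenerate matrix: no dispersion signal")
    return(structure(list(gene_ids = character(), dispersion_z = disp,
                          mean_bins = rep(NA_integer_, length(mu)),
                          ln_mean = ln_mean),
                     class = "variable_gene_set"))
  }
  bins <- if (n_bins <= 1) rep(1L, length(ln_mean)) else
    as.integer(cut(ln_mean, breaks = n_bins, include.lowest = TRUE))
  z <- disp
  for (b in unique(bins[!is.na(bins)])) {
    idx <- which(bins == b)
    s <- sd(disp[idx])
    z[idx] <- if (is.na(s) || s == 0) 0 else (disp[idx] - mean(disp[idx])) / s
  }
  sel <- z >= z_cutoff & ln_mean >= mean_bounds[1] & ln_mean <= mean_bounds[2]
  structure(list(gene_ids = nm$gene_ids[sel], dispersion_z = setNames(z, nm$gene_ids),
                 mean_bins = setNames(bins, nm$gene_ids),
                 ln_mean = setNames(ln_mean, nm$gene_ids)),
            class = "variable_gene_set")
}

#' @export
print.variable_gene_set <- function(x, ...) {
  cat(sprintf("variable_gene_set: %d genes selected of %d\n",
              length(x$gene_ids), length(x$dispersion_z)))
  invisible(x)
}

#' Center and scale genes
#'
#' Per-gene standardization of a normalized matrix: each gene is centered to
#' mean 0 and scaled to unit sample SD (n - 1 denominator); genes with zero
#' SD are set to 0 and values are clipped to `c(-clip, clip)`.
#'
#' @param nm a [normalized_matrix()] (or a plain genes x cells matrix).
#' @param clip symmetric clipping bound.
#' @return A dense genes x cells matrix of scaled values.
#' @export
scale_genes <- function(nm, clip = 10) {
  v <- if (inherits(nm, "normalized_matrix")) as.matrix(nm$values) else
    as.matrix(nm)
  stopifnot(ncol(v) >= 2)
  ctr <- rowMeans(v)
  s <- apply(v, 1, sd)
  z <- (v - ctr) / ifelse(s == 0, 1, s)
  z[s == 0, ] <- 0
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  z
}
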