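#' Parameters for balanced trajectory analysis
#'
#' @param n_per_stage cells of the majority lineage sampled per stage (250
#'   for the human datasets, 80 for mouse, mirroring the relative size of
#'   the cholangiocyte population).
#' @param n_pcs number of principal components.
#' @param pc_gene_corr_cutoff |Pearson r| cut-off defining PC-related genes.
#' @param cc_n_bins expression-magnitude bins for cell-cycle control gene
#'   matching (default 10).
#' @param cc_gene_corr_cutoff genes correlating above this |r| with either
#'   cycle score are removed before trajectory PCA.
#' @param var_z_cutoff dispersion z cut-off for the trajectory's
#'   variable-gene selection. Deliberately more permissive than the
#'   clustering default (1): genes changing gradually and monotonically
#'   along a continuum have modest dispersion, and an inclusive gene set is
#'   required for the maturation axis to dominate the leading component.
#' @param seed integer seed.
#' @return A list of class `trajectory_params`.
#' @export
trajectory_params <- function(n_per_stage = 250, n_pcs = 20,
                              pc_gene_corr_cutoff = 0.3, cc_n_bins = 10,
                              cc_gene_corr_cutoff = 0.3, var_z_cutoff = 0.25,
                              seed = 1) {
  stopifnot(n_per_stage >= 1, n_pcs >= 2,
            pc_gene_corr_cutoff > 0, pc_gene_corr_cutoff < 1)
  structure(as.list(environment()), class = "trajectory_params")
}

#' Balanced-sampling PCA of a differentiation continuum
#'
#' Samples `n_per_stage` cells of the majority lineage
#' (hepatoblasts/hepatocytes) at each stage, keeps every minority-lineage
#' cell (cholangiocytes), finds variable genes on the concatenation,
#' optionally removes cell-cycle-related genes (genes correlated with the S
#' or G2M module score), and runs PCA with stored per-gene center/scale so
#' new cells can be projected into the same space.
#'
#' @param nm a [normalized_matrix()].
#' @param stage stage label per cell (orderable).
#' @param lineage lineage label per cell; the most frequent value is treated
#'   as the majority lineage.
#' @param p a [trajectory_params()].
#' @param s_genes,g2m_genes optional cell-cycle signature gene sets; when
#'   both are given, cycle-correlated genes are removed before PCA.
#' @return A list of class `trajectory_result`: `scores` (cell x PC),
#'   `loadings` (gene x PC), `center_scale`, `cells`, `stage`, `lineage`,
#'   `phase` (when signatures were given), `removed_cc_genes`.
#' @export
balanced_trajectory_pca <- function(nm, stage, lineage,
                                    p = trajectory_params(),
                                    s_genes = NULL, g2m_genes = NULL) {
  stopifnot(inherits(nm, "normalized_matrix"),
            length(stage) == ncol(nm$values),
            length(lineage) == ncol(nm$values))
  lineage <- as.character(lineage)
  major <- names(which.max(table(lineage)))
  if (length(unique(lineage)) < 2)
    warning("single lineage present: no branch cells to keep")
  seeds <- derive_seeds(p$seed, length(unique(stage)) + 1)
  keep <- integer()
  stages <- sort(unique(stage))
  for (i in seq_along(stages)) {
    idx <- which(stage == stages[i] & lineage == major)
    if (length(idx) > p$n_per_stage)
      idx <- withr::with_seed(seeds[i], sample(idx, p$n_per_stage))
    else if (length(idx) < p$n_per_stage)
      warning(sprintf("stage '%s' has %d < %d majority cells; taking all",
                      stages[i], length(idx), p$n_per_stage))
    keep <- c(keep, idx)
  }
  keep <- sort(c(keep, which(lineage != major)))
  v <- nm$values[, keep, drop = FALSE]
  sub_nm <- normalized_matrix(v, nm$norm_kind, nm$scale_factor,
                              nm$cell_meta[keep, , drop = FALSE])
  vg <- find_variable_genes(sub_nm, z_cutoff = p$var_z_cutoff)
  genes <- vg$gene_ids
  if (length(genes) < p$n_pcs + 1)
    genes <- names(sort(vg$dispersion_z, decreasing = TRUE))[
      seq_len(min(500, nrow(v)))]
  phase <- NULL
  removed <- character()
  if (!is.null(s_genes) && !is.null(g2m_genes)) {
    cc <- cell_cycle_score(sub_nm, s_genes, g2m_genes,
                           n_bins = p$cc_n_bins, seed = seeds[length(seeds)])
    phase <- cc$phase
    dense <- as.matrix(v[genes, , drop = FALSE])
    r_s <- apply(dense, 1, function(x)
      if (sd(x) == 0) 0 else cor(x, cc$s_score))
    r_g <- apply(dense, 1, function(x)
      if (sd(x) == 0) 0 else cor(x, cc$g2m_score))
    removed <- genes[abs(r_s) > p$cc_gene_corr_cutoff |
                     abs(r_g) > p$cc_gene_corr_cutoff]
    genes <- setdiff(genes, removed)
  }
  emb <- run_pca(v, genes = genes, n_pcs = min(p$n_pcs, length(genes) - 1))
  structure(list(scores = emb$scores, loadings = emb$loadings,
                 center_scale = list(center = emb$center, scale = emb$scale,
                                     clip = emb$clip, genes = emb$genes),
                 cells = colnames(v)[seq_len(ncol(v))],
                 stage = stage[keep], lineage = lineage[keep],
                 phase = phase, removed_cc_genes = removed,
                 values = v),
            class = "trajectory_result")
}

#' @export
print.trajectory_result <- function(x, ...) {
  cat(sprintf("trajectory_result: %d cells x %d PCs (%d genes)\n",
              nrow(x$scores), ncol(x$scores),
              length(x$center_scale$genes)))
  invisible(x)
}

#' Genes correlated with a principal component
#'
#' Pearson correlation between a PC's per-cell scores and each gene's
#' expression; genes with `|r| >= cutoff` are returned with the sign of r.
#'
#' @param tr a `trajectory_result`.
#' @param nm a [normalized_matrix()] restricted to the trajectory cells (or
#'   `NULL` to use the values stored in `tr`).
#' @param pc_index which PC.
#' @param cutoff |r| threshold.
#' @return data.frame with `gene_id`, `r`, `sign`.
#' @export
pc_related_genes <- function(tr, nm = NULL, pc_index = 1, cutoff = 0.3) {
  stopifnot(pc_index <= ncol(tr$scores))
  v <- if (is.null(nm)) as.matrix(tr$values) else as.matrix(nm$values)
  stopifnot(ncol(v) == nrow(tr$scores))
  score <- tr$scores[, pc_index]
  r <- apply(v, 1, function(x) if (sd(x) == 0) 0 else cor(x, score))
  sel <- abs(r) >= cutoff
  data.frame(gene_id = rownames(v)[sel], r = r[sel],
             sign = ifelse(r[sel] >= 0, "positive", "negative"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cell-cycle phase scoring with expression-matched control bins
#'
#' Module scoring of the S and G2M signatures: each cell's score is the mean
#' signature expression minus the mean expression of a control gene set
#' drawn from `n_bins` expression-magnitude bins matched to the signature
#' genes. A cell is assigned the phase of its larger score when that score
#' is positive, and G1 otherwise.
#'
#' @param nm a [normalized_matrix()].
#' @param s_genes,g2m_genes signature gene sets (missing genes are skipped
#'   with a message).
#' @param n_bins expression-magnitude bins for control matching.
#' @param ctrl_per_gene control genes drawn per signature gene.
#' @param seed integer seed for the control draw.
#' @return A list with `phase` (factor G1/S/G2M per cell), `s_score`,
#'   `g2m_score`.
#' @export
cell_cycle_score <- function(nm, s_genes, g2m_genes, n_bins = 10,
                             ctrl_per_gene = 100, seed = 1) {
  stopifnot(inherits(nm, "normalized_matrix"))
  v <- as.matrix(nm$values)
  miss <- setdiff(c(s_genes, g2m_genes), rownames(v))
  if (length(miss))
    message("skipping ", length(miss), " signature genes absent from matrix")
  s_genes <- intersect(s_genes, rownames(v))
  g2m_genes <- intersect(g2m_genes, rownames(v))
  stopifnot(length(s_genes) >= 2, length(g2m_genes) >= 2)
  avg <- rowMeans(v)
  brk <- quantile(avg, probs = seq(0, 1, length.out = n_bins + 1))
  brk <- unique(brk)
  bins <- as.integer(cut(avg, breaks = brk, include.lowest = TRUE))
  module_score <- function(sig, seed_off) {
    ctrl <- withr::with_seed(seed + seed_off, unique(unlist(
      lapply(sig, function(g) {
        pool <- setdiff(names(avg)[bins == bins[match(g, names(avg))]], sig)
        if (!length(pool)) return(character())
        sample(pool, min(ctrl_per_gene, length(pool)))
      }))))
    if (!length(ctrl)) stop("no control genes available for scoring")
    colMeans(v[sig, , drop = FALSE]) - colMeans(v[ctrl, , drop = FALSE])
  }
  s_score <- module_score(s_genes, 0)
  g2m_score <- module_score(g2m_genes, 1)
  phase <- ifelse(pmax(s_score, g2m_score) <= 0, "G1",
                  ifelse(s_score > g2m_score, "S", "G2M"))
  list(phase = factor(phase, levels = c("G1", "S", "G2M")),
       s_score = s_score, g2m_score = g2m_score)
}

#' Fraction of proliferative cells per stage
#'
#' The proliferative fraction of a stage is the proportion of its cells in
#' S or G2M phase.
#'
#' @param phases per-cell phases (`G1`/`S`/`G2M`).
#' @param stage stage label per cell.
#' @return Named numeric vector of fractions in stage order.
#' @export
proliferative_fraction <- function(phases, stage) {
  stopifnot(length(phases) == length(stage))
  prolif <- phases %in% c("S", "G2M")
  out <- tapply(prolif, stage, mean)
  out[order(names(out))]
}

#' Detect an expression switch between consecutive stages
#'
#' Computes per-stage mean expression profiles (over the supplied genes),
#' clusters the stages by average-linkage hierarchical clustering on
#' correlation distance, and maps the dendrogram's top bipartition onto the
#' temporal order. A bipartition contiguous in time defines the switch
#' boundary (the stage pair it separates); a non-contiguous bipartition is
#' reported as such with `boundary = NA` rather than guessed.
#'
#' The split's `depth`, `1 - h2/h1` with `h1 >= h2` the two highest merge
#' heights, measures how much the top bipartition dominates the dendrogram;
#' stage-exchangeable data produce shallow splits (depth near 0) while a
#' planted transition produces a deep one, and `confident` flags splits
#' with `depth >= min_depth`. Note that a smooth monotone drift also
#' produces a deep contiguous split: stage-profile clustering cannot by
#' itself distinguish an abrupt switch from fast gradual change.
#'
#' @param nm a [normalized_matrix()] (or genes x cells matrix).
#' @param stage stage label per cell.
#' @param ordered_stages stages in temporal order (default: sorted unique).
#' @param genes genes to profile (default: all).
#' @param min_depth minimal split depth for `confident`.
#' @return A list of class `stage_switch`: `boundary` (index pair into
#'   `ordered_stages`, or NA), `contiguous`, `depth`, `confident`, `split`
#'   (stage membership of the top bipartition), `profiles`.
#' @export
stage_switch <- function(nm, stage, ordered_stages = NULL, genes = NULL,
                         min_depth = 0.25) {
  v <- if (inherits(nm, "normalized_matrix")) as.matrix(nm$values) else
    as.matrix(nm)
  stopifnot(length(stage) == ncol(v))
  if (is.null(ordered_stages)) ordered_stages <- sort(unique(stage))
  stopifnot(length(ordered_stages) >= 2)
  if (!is.null(genes)) v <- v[intersect(genes, rownames(v)), , drop = FALSE]
  prof <- vapply(ordered_stages, function(s)
    rowMeans(v[, stage == s, drop = FALSE]), numeric(nrow(v)))
  colnames(prof) <- as.character(ordered_stages)
  keep <- apply(prof, 1, sd) > 0
  prof_v <- prof[keep, , drop = FALSE]
  if (length(ordered_stages) == 2) {
    return(structure(list(boundary = c(1L, 2L), contiguous = TRUE,
                          depth = 1, confident = TRUE,
                          split = setNames(c(1L, 2L),
                                           as.character(ordered_stages)),
                          profiles = prof),
                     class = "stage_switch"))
  }
  d <- as.dist(1 - cor(prof_v))
  hc <- hclust(d, method = "average")
  h <- sort(hc$height, decreasing = TRUE)
  depth <- if (h[1] <= 0) 0 else 1 - h[2] / h[1]
  split <- cutree(hc, k = 2)
  block <- split[as.character(ordered_stages)]
  changes <- unname(which(diff(block) != 0))
  if (length(changes) != 1) {
    warning("top bipartition of stages is not contiguous in time; ",
            "no switch boundary reported")
    return(structure(list(boundary = c(NA_integer_, NA_integer_),
                          contiguous = FALSE, depth = depth,
                          confident = FALSE, split = block,
                          profiles = prof),
                     class = "stage_switch"))
  }
  structure(list(boundary = c(changes, changes + 1L), contiguous = TRUE,
                 depth = depth, confident = depth >= min_depth,
                 split = block, profiles = prof),
            class = "stage_switch")
}

#' @export
print.stage_switch <- function(x, ...) {
  if (x$contiguous)
    cat(sprintf("stage_switch: boundary between ordered stages %d and %d\n",
                x$boundary[1], x$boundary[2]))
  else cat("stage_switch: no contiguous boundary detected\n")
  invisible(x)
}

#' Combine two species into one scaled PCA space
#'
#' Restricts both matrices to their one-to-one orthologues (dropping
#' species-specific genes), z-scales genes within each species separately to
#' remove species-level offsets, concatenates the cells, and runs PCA on the
#' union of the two species' variable-gene sets.
#'
#' @param nm_a,nm_b [normalized_matrix()] objects.
#' @param ortho an [orthologue_map()].
#' @param n_pcs number of PCs.
#' @param clip scaling clip bound.
#' @param var_z_cutoff dispersion z cut-off for the per-species
#'   variable-gene selection (permissive, as for trajectory PCA).
#' @return A list of class `combined_pca`: `scores`, `loadings`, `species`,
#'   `genes` (orthologue pairs used), `var_genes`.
#' @export
combine_species <- function(nm_a, nm_b, ortho, n_pcs = 20, clip = 10,
                            var_z_cutoff = 0.25) {
  stopifnot(inherits(ortho, "orthologue_map"))
  pairs <- ortho$pairs
  pairs <- pairs[pairs$gene_a %in% nm_a$gene_ids &
                 pairs$gene_b %in% nm_b$gene_ids, ]
  if (nrow(pairs) < n_pcs) stop("fewer shared orthologues than n_pcs")
  va <- nm_a$values[pairs$gene_a, , drop = FALSE]
  vb <- nm_b$values[pairs$gene_b, , drop = FALSE]
  vg_a <- find_variable_genes(normalized_matrix(va, nm_a$norm_kind,
                                                nm_a$scale_factor),
                              z_cutoff = var_z_cutoff)
  vg_b <- find_variable_genes(normalized_matrix(vb, nm_b$norm_kind,
                                                nm_b$scale_factor),
                              z_cutoff = var_z_cutoff)
  var_union <- union(vg_a$gene_ids,
                     pairs$gene_a[match(vg_b$gene_ids, pairs$gene_b)])
  var_union <- var_union[!is.na(var_union)]
  if (length(var_union) < n_pcs) var_union <- pairs$gene_a
  za <- scale_genes(va, clip)
  zb <- scale_genes(vb, clip)
  rownames(zb) <- pairs$gene_a        # shared orthologue namespace
  comb <- cbind(za, zb)
  pc <- prcomp(t(comb[var_union, , drop = FALSE]), center = FALSE,
               scale. = FALSE,
               rank. = min(n_pcs, length(var_union) - 1, ncol(comb) - 1))
  scores <- pc$x
  loadings <- pc$rotation
  for (j in seq_len(ncol(loadings))) {
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 species = c(rep("A", ncol(za)), rep("B", ncol(zb))),
                 genes = pairs, var_genes = var_union),
            class = "combined_pca")
}

#' Project new cells into a trained trajectory PCA space
#'
#' Centers and scales the new cells' expression with the training
#' statistics stored in a `trajectory_result` and multiplies by the stored
#' loadings. Genes missing from the new matrix contribute 0 after scaling
#' (the training mean); the overlap is reported via a message.
#'
#' @param nm a [normalized_matrix()] of the new cells.
#' @param tr a `trajectory_result` from [balanced_trajectory_pca()].
#' @return Cells x PCs coordinate matrix.
#' @export
project_cells <- function(nm, tr) {
  cs <- tr$center_scale
  v <- if (inherits(nm, "normalized_matrix")) as.matrix(nm$values) else
    as.matrix(nm)
  present <- intersect(cs$genes, rownames(v))
  if (length(present) < length(cs$genes))
    message(sprintf("projection uses %d of %d training genes",
                    length(present), length(cs$genes)))
  z <- matrix(0, length(cs$genes), ncol(v),
              dimnames = list(cs$genes, colnames(v)))
  z[present, ] <- (v[present, , drop = FALSE] - cs$center[present]) /
    cs$scale[present]
  z[z > cs$clip] <- cs$clip
  z[z < -cs$clip] <- -cs$clip
  t(z) %*% tr$loadings
}

#' Classify cells into two groups from PC-related genes
#'
#' Scores each cell as the mean expression of the positive-sign PC-related
#' genes minus the mean of the negative-sign set, then splits the scores
#' with 2-class k-means. Bimodality is accepted only when a two-component
#' Gaussian mixture beats a single Gaussian by more than `bic_margin` BIC
#' units (a silhouette cut cannot serve here: splitting a unimodal 1-D
#' distribution at its centre already yields silhouettes around 0.5).
#' Group labels `low`/`high` follow score order, not cluster index.
#'
#' @param nm a [normalized_matrix()] of the cells (or NULL to use the
#'   trajectory's stored values).
#' @param tr a `trajectory_result`.
#' @param pc_index which PC's related genes to use.
#' @param cutoff |r| cut-off for [pc_related_genes()].
#' @param bic_margin required BIC advantage of the 2-component mixture.
#' @param seed integer seed for k-means.
#' @return A list of class `bimodal_groups`: `group` (`low`/`high`/NA per
#'   cell), `score`, `delta_bic`, `bimodal` flag.
#' @export
classify_bimodal_groups <- function(tr, nm = NULL, pc_index = 2,
                                    cutoff = 0.3, bic_margin = 10,
                                    seed = 1) {
  prg <- pc_related_genes(tr, nm, pc_index, cutoff)
  v <- if (is.null(nm)) as.matrix(tr$values) else as.matrix(nm$values)
  if (nrow(prg) < 2) {
    message("fewer than 2 PC-related genes at the requested cutoff: ",
            "no bimodality")
    return(structure(list(group = rep(NA_character_, ncol(v)),
                          score = rep(NA_real_, ncol(v)),
                          delta_bic = NA_real_, bimodal = FALSE),
                     class = "bimodal_groups"))
  }
  pos <- prg$gene_id[prg$sign == "positive"]
  neg <- prg$gene_id[prg$sign == "negative"]
  score <- numeric(ncol(v))
  if (length(pos)) score <- score + colMeans(v[pos, , drop = FALSE])
  if (length(neg)) score <- score - colMeans(v[neg, , drop = FALSE])
  km <- withr::with_seed(seed, kmeans(score, centers = 2, nstart = 10))
  delta_bic <- mixture_bic_advantage(score, km$cluster)
  if (delta_bic < bic_margin) {
    return(structure(list(group = rep(NA_character_, length(score)),
                          score = score, delta_bic = delta_bic,
                          bimodal = FALSE),
                     class = "bimodal_groups"))
  }
  hi_cluster <- which.max(km$centers)
  group <- ifelse(km$cluster == hi_cluster, "high", "low")
  structure(list(group = setNames(group, colnames(v)), score = score,
                 delta_bic = delta_bic, bimodal = TRUE),
            class = "bimodal_groups")
}

# BIC advantage of a two-component Gaussian mixture (EM, initialized from a
# k-means split) over a single Gaussian fit of a 1-D score.
mixture_bic_advantage <- function(x, init_cluster, n_iter = 100) {
  n <- length(x)
  sd_mle <- function(v) sqrt(mean((v - mean(v))^2))
  ll1 <- sum(dnorm(x, mean(x), max(sd_mle(x), 1e-8), log = TRUE))
  bic1 <- -2 * ll1 + 2 * log(n)
  w <- mean(init_cluster == 1)
  mu <- c(mean(x[init_cluster == 1]), mean(x[init_cluster != 1]))
  s <- pmax(c(sd_mle(x[init_cluster == 1]), sd_mle(x[init_cluster != 1])),
            1e-3 * sd_mle(x))
  for (i in seq_len(n_iter)) {
    d1 <- w * dnorm(x, mu[1], s[1])
    d2 <- (1 - w) * dnorm(x, mu[2], s[2])
    g <- d1 / pmax(d1 + d2, 1e-300)
    w <- mean(g)
    mu <- c(sum(g * x) / sum(g), sum((1 - g) * x) / sum(1 - g))
    s <- sqrt(c(sum(g * (x - mu[1])^2) / sum(g),
                sum((1 - g) * (x - mu[2])^2) / sum(1 - g)))
    s <- pmax(s, 1e-4 * sd_mle(x))
  }
  ll2 <- sum(log(pmax(w * dnorm(x, mu[1], s[1]) +
                      (1 - w) * dnorm(x, mu[2], s[2]), 1e-300)))
  bic2 <- -2 * ll2 + 5 * log(n)
  bic1 - bic2
}

#' Diffusion map embedding
#'
#' Gaussian kernel on Euclidean distances (optionally computed in a PCA
#' subspace), density normalization, and row-normalization into a Markov
#' transition matrix whose leading non-trivial right eigenvectors form the
#' embedding. The trivial constant eigenvector (eigenvalue 1) is excluded.
#'
#' @param x cells x features coordinate matrix (e.g. PC scores), or a
#'   [normalized_matrix()] (PCA is then run internally).
#' @param n_components number of diffusion components to return.
#' @param kernel_scale Gaussian kernel bandwidth; default is the median
#'   distance to the 15th nearest neighbour.
#' @param n_pcs PCs used when `x` is a normalized matrix.
#' @param return_operator if `TRUE`, also return the Markov matrix.
#' @return A list of class `diffusion_map`: `coords` (cells x components),
#'   `eigenvalues`, and optionally `operator`.
#' @export
diffusion_map <- function(x, n_components = 2, kernel_scale = NULL,
                          n_pcs = 20, return_operator = FALSE) {
  if (inherits(x, "normalized_matrix")) {
    emb <- run_pca(x$values, n_pcs = min(n_pcs, nrow(x$values) - 1,
                                         ncol(x$values) - 1))
    x <- emb$scores
  }
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(n >= n_components + 2)
  d <- as.matrix(dist(x))
  if (is.null(kernel_scale)) {
    k <- min(15, n - 1)
    kd <- apply(d, 1, function(row) sort(row)[k + 1])
    kernel_scale <- stats::median(kd)
    if (kernel_scale == 0) kernel_scale <- 1
  }
  W <- exp(-d^2 / (2 * kernel_scale^2))
  q <- rowSums(W)
  W <- W / outer(q, q)                  # density normalization (alpha = 1)
  dW <- rowSums(W)
  S <- W / outer(sqrt(dW), sqrt(dW))    # symmetric conjugate of the Markov matrix
  es <- eigen(S, symmetric = TRUE)
  psi <- es$vectors / sqrt(dW)          # right eigenvectors of P
  lambda <- es$values
  comps <- seq(2, n_components + 1)
  coords <- sweep(psi[, comps, drop = FALSE], 2, lambda[comps], "*")
  rownames(coords) <- rownames(x)
  colnames(coords) <- paste0("DC", seq_len(ncol(coords)))
  out <- list(coords = coords, eigenvalues = lambda[comps])
  if (return_operator) out$operator <- W / dW
  structure(out, class = "diffusion_map")
}
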