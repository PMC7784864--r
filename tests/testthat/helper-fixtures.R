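# Lazily-built shared fixtures: generated once per test run, in code.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# Small two-species pair for fast unit tests.
fix_pair_small <- function() fixture("pair_small", function()
  generate_species_pair(sim_config(seed = 101, n_cells_per_type = 60)))

# Default-condition pair for recovery tests.
fix_pair_default <- function() fixture("pair_default", function()
  generate_species_pair(sim_config(seed = 42)))

# Human differentiation trajectory.
fix_traj <- function() fixture("traj", function()
  generate_trajectory(sim_config(seed = 7, n_cells_per_stage = 120),
                      species = "human"))

fix_traj_nm <- function() fixture("traj_nm", function()
  normalize_log(fix_traj()))

# Area under the ROC curve of a score against binary truth.
auroc <- function(score, truth) {
  r <- rank(score)
  n1 <- sum(truth)
  n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Brute-force doublet index: all-pairs distances, exhaustive sort.
brute_doublet_index <- function(coords, is_artificial, k) {
  n <- nrow(coords)
  d <- as.matrix(dist(coords))
  diag(d) <- Inf
  idx <- vapply(seq_len(n), function(i) {
    nn <- order(d[i, ])[seq_len(k)]
    mean(is_artificial[nn])
  }, numeric(1))
  idx[!is_artificial]
}

# Brute-force TOM by the triple-sum formula.
brute_tom <- function(adj) {
  p <- nrow(adj)
  k <- rowSums(adj)
  tom <- diag(p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    l <- sum(vapply(seq_len(p)[-c(i, j)],
                    function(u) adj[i, u] * adj[u, j], numeric(1)))
    tom[i, j] <- (l + adj[i, j]) / (min(k[i], k[j]) + 1 - adj[i, j])
  }
  dimnames(tom) <- dimnames(adj)
  tom
}

# Exhaustive two-sided permutation p-value for the rank-sum statistic.
perm_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (length(pooled) + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  ws <- apply(combs, 2, function(ix) sum(r[ix]))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

# Tiny hand-made normalized matrix.
toy_norm <- function(values, kind = "lnTP10K") {
  normalized_matrix(values, kind, 1e4)
}

traj_fit <- function() {
  fixture("traj_fit", function() {
    tr_m <- fix_traj()
    nm <- fix_traj_nm()
    balanced_trajectory_pca(
      nm, tr_m$cell_meta$stage,
      ifelse(tr_m$cell_meta$truth_branch, "cholangiocyte", "hepatoblast"),
      trajectory_params(n_per_stage = 100, seed = 6),
      s_genes = tr_m$programs$s_genes, g2m_genes = tr_m$programs$g2m_genes)
  })
}

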