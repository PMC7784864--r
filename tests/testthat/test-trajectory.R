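test_that("balanced sampling keeps the quota plus every branch cell", {
  tr_m <- fix_traj()
  tr <- traj_fit()
  n_branch <- sum(tr_m$cell_meta$truth_branch)
  expect_equal(nrow(tr$scores), 6 * 100 + n_branch)
  expect_equal(sum(tr$lineage == "cholangiocyte"), n_branch)
  expect_true(all(table(tr$stage[tr$lineage == "hepatoblast"]) == 100))
})

test_that("PC1 follows the latent maturation axis, PC2 the branch", {
  tr_m <- fix_traj()
  tr <- traj_fit()
  keep <- colnames(tr$values)
  lat <- tr_m$cell_meta[keep, "truth_latent"]
  expect_gt(abs(cor(tr$scores[, 1], lat, method = "spearman")), 0.9)
  br <- tr_m$cell_meta[keep, "truth_branch"]
  expect_gt(abs(cor(tr$scores[, 2], as.numeric(br))), 0.8)
  # branch program drives PC2 loadings
  top_pc2 <- names(sort(abs(tr$loadings[, 2]), decreasing = TRUE))[1:10]
  expect_gt(mean(top_pc2 %in% tr_m$programs$prog_c), 0.8)
})

test_that("cell-cycle-related genes are removed before trajectory PCA", {
  tr_m <- fix_traj()
  tr <- traj_fit()
  cc <- c(tr_m$programs$s_genes, tr_m$programs$g2m_genes)
  expect_lt(mean(cc %in% tr$center_scale$genes), 0.1)
})

test_that("PC-related genes match direct correlation evaluation", {
  tr <- traj_fit()
  prg <- pc_related_genes(tr, pc_index = 1, cutoff = 0.3)
  v <- as.matrix(tr$values)
  # hand evaluation on 5 genes
  for (g in prg$gene_id[1:5]) {
    r <- cor(v[g, ], tr$scores[, 1])
    expect_equal(prg$r[prg$gene_id == g], r, tolerance = 1e-12)
    expect_gte(abs(r), 0.3)
  }
  # a gene equal to the score itself has r = 1
  v2 <- rbind(v[1:20, ], synthetic_score = tr$scores[, 1])
  tr2 <- tr
  tr2$values <- v2
  prg2 <- pc_related_genes(tr2, pc_index = 1, cutoff = 0.3)
  expect_equal(prg2$r[prg2$gene_id == "synthetic_score"], 1,
               tolerance = 1e-12)
  # independent noise is excluded
  v3 <- rbind(v[1:20, ], noise = withr::with_seed(1, rnorm(ncol(v))))
  tr3 <- tr
  tr3$values <- v3
  prg3 <- pc_related_genes(tr3, pc_index = 1, cutoff = 0.3)
  expect_false("noise" %in% prg3$gene_id)
})

test_that("cycle scoring assigns planted phases accurately", {
  tr_m <- fix_traj()
  nm <- fix_traj_nm()
  cc <- cell_cycle_score(nm, tr_m$programs$s_genes, tr_m$programs$g2m_genes,
                         n_bins = 10, seed = 2)
  truth <- tr_m$cell_meta$truth_phase
  expect_gt(mean(as.character(cc$phase) == truth), 0.9)
  # directional checks on hand-built cells
  v <- matrix(0.5, 30, 3,
              dimnames = list(sprintf("g%02d", 1:30), c("s", "g2m", "flat")))
  s_sig <- sprintf("g%02d", 1:5)
  g_sig <- sprintf("g%02d", 6:10)
  v[s_sig, "s"] <- 5
  v[g_sig, "g2m"] <- 5
  sc <- cell_cycle_score(toy_norm(v), s_sig, g_sig, n_bins = 3, seed = 1)
  expect_equal(as.character(sc$phase[["s"]]), "S")
  expect_equal(as.character(sc$phase[["g2m"]]), "G2M")
  expect_equal(as.character(sc$phase[["flat"]]), "G1")
})

test_that("proliferative fractions are computed per stage and decline", {
  expect_equal(unname(proliferative_fraction(c("S", "G1", "G2M", "G1"),
                                             rep(1, 4))), 0.5)
  expect_equal(unname(proliferative_fraction(rep("G1", 5), rep(1, 5))), 0)
  tr <- traj_fit()
  pf <- proliferative_fraction(tr$phase, tr$stage)
  expect_true(all(pf >= 0 & pf <= 1))
  # planted cycling fraction declines from 0.5 to 0.1: recovered fractions
  # are monotone non-increasing within binomial noise
  n_per <- table(tr$stage)
  ci <- 2 * sqrt(pf * (1 - pf) / as.numeric(n_per))
  expect_true(all(diff(pf) <= ci[-length(ci)] + ci[-1]))
  expect_gt(pf[1], pf[6])
})

test_that("stage switch is found at the planted boundary", {
  tr_m <- fix_traj()
  tr <- traj_fit()
  sw <- stage_switch(toy_norm(as.matrix(tr$values)), tr$stage,
                     genes = tr$center_scale$genes)
  expect_true(sw$contiguous)
  expect_equal(sw$boundary, c(4L, 5L))
  # two stages: trivial boundary
  two <- stage_switch(toy_norm(as.matrix(tr$values)),
                      ifelse(tr$stage <= 3, "early", "late"),
                      ordered_stages = c("early", "late"))
  expect_equal(two$boundary, c(1L, 2L))
})

test_that("stage-exchangeable data yield no confident switch", {
  # no planted stage structure at all: the split must be shallow (or
  # non-contiguous), never a confident boundary
  confident <- vapply(1:4, function(i) {
    cfg <- sim_config(seed = 300 + i, n_cells_per_stage = 60,
                      marker_log_fc = 0, switch_log_fc = 0,
                      cc_fraction_start = 0, cc_fraction_end = 0)
    tm <- generate_trajectory(cfg)
    nm <- normalize_log(tm)
    main <- which(!tm$cell_meta$truth_branch)
    sw <- suppressWarnings(
      stage_switch(toy_norm(as.matrix(nm$values[, main])),
                   tm$cell_meta$stage[main]))
    isTRUE(sw$confident)
  }, logical(1))
  expect_lte(mean(confident), 0.25)
})

test_that("species combination removes species offsets and shares PC1", {
  # same master seed = same planted programs on orthologous genes; the
  # different per-stage cell counts decouple the two species' cells
  cfg <- sim_config(seed = 21, n_cells_per_stage = 100, vtn_bimodal = FALSE)
  h <- generate_trajectory(cfg, species = "human")
  cfg_m <- sim_config(seed = 21, n_cells_per_stage = 80,
                      vtn_bimodal = FALSE)
  m <- generate_trajectory(cfg_m, species = "mouse")
  om <- orthologue_map(data.frame(a = h$gene_ids, b = m$gene_ids))
  nm_h <- normalize_log(h)
  nm_m <- normalize_log(m)
  comb <- combine_species(nm_h, nm_m, om, n_pcs = 10)
  # per-species gene means are centred by the per-species scaling
  # (exactly without clipping; clipping perturbs only extreme sparse genes)
  expect_lt(max(abs(rowMeans(
    scale_genes(nm_h$values[comb$genes$gene_a, ], clip = Inf)))), 1e-10)
  expect_lt(max(abs(rowMeans(
    scale_genes(nm_h$values[comb$genes$gene_a, ])))), 0.1)
  # PC1 tracks the planted axis within both species
  lat_h <- h$cell_meta$truth_latent
  lat_m <- m$cell_meta$truth_latent
  pc1 <- comb$scores[, 1]
  is_a <- comb$species == "A"
  expect_gt(abs(cor(pc1[is_a], lat_h, method = "spearman")), 0.8)
  expect_gt(abs(cor(pc1[!is_a], lat_m, method = "spearman")), 0.8)
})

test_that("a relabeled copy of one species shows no species axis", {
  h <- generate_trajectory(sim_config(seed = 23, n_cells_per_stage = 60))
  nm_h <- normalize_log(h)
  vb <- nm_h$values
  colnames(vb) <- paste0("copy_", colnames(vb))
  nm_b <- normalized_matrix(vb, nm_h$norm_kind, nm_h$scale_factor)
  om <- orthologue_map(data.frame(a = h$gene_ids, b = h$gene_ids))
  comb <- combine_species(nm_h, nm_b, om, n_pcs = 5)
  for (j in 1:5)
    expect_lt(abs(cor(comb$scores[, j],
                      as.numeric(comb$species == "A"))), 0.1)
})

test_that("projection reproduces training scores and is linear", {
  tr <- traj_fit()
  nm_train <- toy_norm(as.matrix(tr$values))
  proj <- project_cells(nm_train, tr)
  expect_lt(max(abs(proj - tr$scores)), 1e-8)
  # the training mean profile projects to the origin
  mean_prof <- matrix(rowMeans(as.matrix(tr$values)), ncol = 1,
                      dimnames = list(rownames(tr$values), "meancell"))
  expect_lt(max(abs(project_cells(toy_norm(mean_prof), tr))), 1e-8)
  # linearity on unclipped cells
  v <- as.matrix(tr$values)[, 1:2]
  blend <- 0.3 * v[, 1] + 0.7 * v[, 2]
  pv <- project_cells(toy_norm(cbind(v, blend = blend)), tr)
  expect_equal(unname(pv["blend", ]),
               unname(0.3 * pv[1, ] + 0.7 * pv[2, ]), tolerance = 1e-6)
})

test_that("held-out branch cells project onto the branch region", {
  tr_m <- fix_traj()
  nm <- fix_traj_nm()
  # hold out a third of the branch cells, train on the rest, project back
  branch_idx <- which(tr_m$cell_meta$truth_branch)
  held <- branch_idx[seq(1, length(branch_idx), by = 3)]
  train <- setdiff(seq_len(ncol(nm$values)), held)
  nm_train <- normalized_matrix(nm$values[, train], "lnTP10K", 1e4,
                                tr_m$cell_meta[train, ])
  lin <- ifelse(tr_m$cell_meta$truth_branch, "cholangiocyte", "hepatoblast")
  tr <- balanced_trajectory_pca(
    nm_train, tr_m$cell_meta$stage[train], lin[train],
    trajectory_params(n_per_stage = 100, seed = 6),
    s_genes = tr_m$programs$s_genes, g2m_genes = tr_m$programs$g2m_genes)
  proj <- project_cells(
    normalized_matrix(nm$values[, held, drop = FALSE], "lnTP10K", 1e4), tr)
  fit_branch <- tr$lineage == "cholangiocyte"
  cen_branch <- colMeans(tr$scores[fit_branch, 1:2])
  cen_main <- colMeans(tr$scores[!fit_branch, 1:2])
  d_branch <- sqrt(rowSums(sweep(proj[, 1:2, drop = FALSE], 2,
                                 cen_branch)^2))
  d_main <- sqrt(rowSums(sweep(proj[, 1:2, drop = FALSE], 2, cen_main)^2))
  expect_gt(mean(d_branch < d_main), 0.9)
})

test_that("bimodal late-stage groups are recovered, unimodal data flagged", {
  tr_m <- fix_traj()
  nm <- fix_traj_nm()
  quiescent <- which(!tr_m$cell_meta$truth_branch &
                     tr_m$cell_meta$truth_phase == "G1")
  nm_q <- normalized_matrix(nm$values[, quiescent], "lnTP10K", 1e4,
                            tr_m$cell_meta[quiescent, ])
  tr_q <- suppressWarnings(balanced_trajectory_pca(
    nm_q, tr_m$cell_meta$stage[quiescent],
    rep("hepatoblast", length(quiescent)),
    trajectory_params(n_per_stage = 250, seed = 2),
    s_genes = tr_m$programs$s_genes, g2m_genes = tr_m$programs$g2m_genes))
  bg <- classify_bimodal_groups(tr_q, pc_index = 2, cutoff = 0.4)
  expect_true(bg$bimodal)
  truth <- tr_m$cell_meta[colnames(tr_q$values), "truth_group"]
  late <- !is.na(truth)
  expect_gt(adjusted_rand_index(bg$group[late], truth[late]), 0.9)
  # labels follow score order
  expect_gt(mean(bg$score[bg$group == "high"]),
            mean(bg$score[bg$group == "low"]))
  # unimodal control: no bimodal program, and none of the other planted
  # two-group structures (subpopulation, switch) that PC2 could latch onto
  cfg0 <- sim_config(seed = 8, n_cells_per_stage = 100, vtn_bimodal = FALSE,
                     rare_subpop_fraction = c(human = 0, mouse = 0),
                     switch_log_fc = 0)
  t0 <- generate_trajectory(cfg0)
  nm0 <- normalize_log(t0)
  q0 <- which(!t0$cell_meta$truth_branch & t0$cell_meta$truth_phase == "G1")
  nm0q <- normalized_matrix(nm0$values[, q0], "lnTP10K", 1e4)
  tr0 <- suppressWarnings(balanced_trajectory_pca(
    nm0q, t0$cell_meta$stage[q0], rep("hepatoblast", length(q0)),
    trajectory_params(n_per_stage = 250, seed = 2),
    s_genes = t0$programs$s_genes, g2m_genes = t0$programs$g2m_genes))
  bg0 <- classify_bimodal_groups(tr0, pc_index = 2, cutoff = 0.4)
  expect_false(bg0$bimodal)
})

test_that("diffusion map is a proper Markov embedding of the path", {
  tr <- traj_fit()
  main <- tr$lineage == "hepatoblast"
  sc <- tr$scores[main, 1:10]
  dm <- diffusion_map(sc, n_components = 2, return_operator = TRUE)
  expect_equal(unname(rowSums(dm$operator)), rep(1, nrow(sc)),
               tolerance = 1e-10)
  expect_true(all(dm$eigenvalues < 1 - 1e-8))
  tr_m <- fix_traj()
  lat <- tr_m$cell_meta[rownames(sc), "truth_latent"]
  expect_gt(abs(cor(dm$coords[, 1], lat, method = "spearman")), 0.9)
})
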