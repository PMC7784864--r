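test_that("SNN weight of cells sharing all neighbours is 1", {
  # two coincident points in a tight cluster share their full kNN sets
  set.seed(1)
  coords <- rbind(c(0, 0), c(1e-9, 0), matrix(rnorm(20, 10), ncol = 2))
  g <- crossliver:::snn_graph(coords, k_neighbors = 5, prune = 0)
  expect_equal(g[1, 2], 1)
})

test_that("two planted blobs are recovered, one blob stays whole", {
  pair <- generate_species_pair(sim_config(seed = 61, n_cell_types = 2,
                                           n_families = 2,
                                           n_cells_per_type = 150))
  nm <- normalize_log(pair$human)
  cl <- snn_cluster(nm, seed = 2)
  truth <- pair$human$cell_meta$truth_type
  expect_length(unique(cl$labels), 2)
  expect_gt(adjusted_rand_index(cl$labels, truth), 0.95)
  # single blob: no planted contrast, one cluster at default resolution
  one <- generate_species_pair(sim_config(seed = 62, n_cell_types = 2,
                                          n_families = 2, marker_log_fc = 0,
                                          batch_shift_sd = 0,
                                          n_cells_per_type = 150))
  cl1 <- snn_cluster(normalize_log(one$human), seed = 2)
  expect_length(unique(cl1$labels), 1)
})

test_that("clustering is deterministic under a fixed seed", {
  nm <- normalize_log(fix_pair_small()$human)
  a <- snn_cluster(nm, seed = 9)
  b <- snn_cluster(nm, seed = 9)
  expect_identical(a$labels, b$labels)
})

test_that("iterative subclustering recovers subtypes with namespaced labels", {
  pair <- fix_pair_small()
  m <- pair$human
  fam <- m$cell_meta$truth_family
  sub <- iterative_subcluster(m, fam, subsets = "erythroid", seed = 3)
  ery <- fam == "erythroid"
  expect_true(all(startsWith(sub$labels[ery], "erythroid.")))
  expect_true(all(sub$labels[!ery] == fam[!ery]))
  expect_equal(unique(sub$round[ery]), 2L)
  got <- adjusted_rand_index(sub$labels[ery],
                             m$cell_meta$truth_type[ery])
  expect_gt(got, 0.95)
})

test_that("batch centering aligns batch means and keeps biology", {
  set.seed(5)
  emb <- matrix(rnorm(400), ncol = 2)
  batch <- rep(c("b1", "b2"), each = 100)
  shifted <- emb
  shifted[batch == "b2", 1] <- shifted[batch == "b2", 1] + 5
  corr <- batch_center(shifted, batch)
  m1 <- colMeans(corr[batch == "b1", ])
  m2 <- colMeans(corr[batch == "b2", ])
  expect_equal(m1, m2, tolerance = 1e-10)
  expect_equal(colMeans(corr), colMeans(shifted), tolerance = 1e-10)
  # single batch: identity
  expect_identical(batch_center(emb, rep("b", 200)), emb)
  # orthogonal batch shift does not destroy planted cluster structure
  types <- rep(c(0, 8), each = 100)
  emb2 <- cbind(types + rnorm(200, sd = 0.5), rnorm(200))
  batch2 <- rep(c("x", "y"), 100)
  emb2[batch2 == "y", 2] <- emb2[batch2 == "y", 2] + 4
  corr2 <- batch_center(emb2, batch2)
  km_before <- kmeans(emb2[, 1], 2)$cluster
  km_after <- kmeans(corr2[, 1], 2)$cluster
  expect_gt(adjusted_rand_index(km_after, types), 0.95)
  expect_equal(adjusted_rand_index(km_after, types),
               adjusted_rand_index(km_before, types), tolerance = 0.05)
})

test_that("marker-panel annotation assigns planted types", {
  pair <- fix_pair_small()
  nm <- normalize_log(pair$human)
  truth <- pair$human$cell_meta$truth_type
  cl <- snn_cluster(nm, seed = 4)
  ann <- annotate_clusters(nm, cl$labels, pair$truth$marker_panel)
  expect_setequal(unique(unname(ann)), pair$truth$types$type)
  # per-cell agreement with the planted type
  per_cell <- unname(ann[cl$labels])
  expect_gt(mean(per_cell == truth), 0.98)
})

test_that("annotation handles hepatic markers, ties and missing genes", {
  # cluster 1 expresses the hepatoblast panel genes, cluster 2 nothing
  v <- matrix(0, 3, 6, dimnames = list(c("HNF4A", "AFP", "SPP1"),
                                       paste0("c", 1:6)))
  v[c("HNF4A", "AFP"), 1:3] <- 3
  v["SPP1", 4:6] <- 3
  nm <- toy_norm(v)
  panel <- data.frame(type = c("hepatoblast_hepatocyte",
                               "hepatoblast_hepatocyte", "cholangiocyte"),
                      gene_id = c("HNF4A", "AFP", "SPP1"))
  lab <- rep(c("1", "2"), each = 3)
  ann <- annotate_clusters(nm, lab, panel)
  expect_equal(unname(ann["1"]), "hepatoblast_hepatocyte")
  expect_equal(unname(ann["2"]), "cholangiocyte")
  # all scores tied: unassigned with a warning
  v0 <- matrix(1, 2, 4, dimnames = list(c("g1", "g2"), paste0("c", 1:4)))
  panel0 <- data.frame(type = c("t1", "t2"), gene_id = c("g1", "g2"))
  expect_warning(ann0 <- annotate_clusters(toy_norm(v0),
                                           rep(c("1", "2"), 2), panel0),
                 "unassigned")
  expect_true(all(ann0 == "unassigned"))
  # missing panel genes are skipped with a message
  panel_m <- rbind(panel, data.frame(type = "ghost", gene_id = "NOPE"))
  expect_message(annotate_clusters(nm, lab, panel_m), "skipping")
})

test_that("cross-species type correlation matches hand computation", {
  # 2 types x 4 orthologues, hand-built means; no standardization
  va <- matrix(0, 4, 4, dimnames = list(paste0("g", 1:4), paste0("a", 1:4)))
  vb <- va
  dimnames(vb) <- list(paste0("g", 1:4), paste0("b", 1:4))
  va[, 1:2] <- c(1, 2, 3, 4); va[, 3:4] <- c(4, 3, 2, 1)
  vb[, 1:2] <- c(1, 2, 3, 5); vb[, 3:4] <- c(5, 3, 2, 1)
  om <- orthologue_map(data.frame(a = paste0("g", 1:4), b = paste0("g", 1:4)))
  tc <- crossspecies_type_correlation(toy_norm(va), toy_norm(vb),
                                      rep(c("t1", "t2"), each = 2),
                                      rep(c("t1", "t2"), each = 2),
                                      om, standardize = FALSE)
  expect_equal(tc$corr["t1", "t1"], cor(c(1, 2, 3, 4), c(1, 2, 3, 5)),
               tolerance = 1e-12)
  expect_equal(tc$corr["t1", "t2"], cor(c(1, 2, 3, 4), c(5, 3, 2, 1)),
               tolerance = 1e-12)
  # identical matrices through the map: unit diagonal
  tc_id <- crossspecies_type_correlation(toy_norm(va), {
    vb2 <- va; dimnames(vb2) <- dimnames(vb); toy_norm(vb2)
  }, rep(c("t1", "t2"), each = 2), rep(c("t1", "t2"), each = 2),
    om, standardize = FALSE)
  expect_equal(unname(diag(tc_id$corr)), c(1, 1), tolerance = 1e-12)
})

test_that("independent noise profiles correlate near zero", {
  set.seed(11)
  va <- matrix(abs(rnorm(200 * 40)), 200,
               dimnames = list(sprintf("g%03d", 1:200), paste0("a", 1:40)))
  vb <- matrix(abs(rnorm(200 * 40)), 200,
               dimnames = list(sprintf("g%03d", 1:200), paste0("b", 1:40)))
  om <- orthologue_map(data.frame(a = rownames(va), b = rownames(va)))
  tc <- crossspecies_type_correlation(toy_norm(va), toy_norm(vb),
                                      rep(c("t1", "t2"), 20),
                                      rep(c("t1", "t2"), 20), om)
  expect_lt(max(abs(tc$corr)), 0.3)
})

test_that("family grouping recovers planted blocks and is label-stable", {
  # block-diagonal correlation with 4 planted blocks
  blocks <- rep(1:4, each = 3)
  corr <- outer(blocks, blocks, function(a, b) ifelse(a == b, 0.9, 0.1))
  diag(corr) <- 1
  rownames(corr) <- colnames(corr) <- sprintf("T%02d", 1:12)
  fam <- family_grouping(corr, 4)
  expect_equal(adjusted_rand_index(fam, blocks), 1)
  # n_families = n_types: singletons
  expect_length(unique(family_grouping(corr, 12)), 12)
  # permuting type order leaves family composition unchanged
  perm <- withr::with_seed(2, sample(12))
  fam_p <- family_grouping(corr[perm, perm], 4)
  expect_equal(adjusted_rand_index(fam_p[rownames(corr)], fam), 1)
})

test_that("full pipeline recovers 13 types and 4 families", {
  pair <- fix_pair_default()
  nm_h <- normalize_log(pair$human)
  nm_m <- normalize_log(pair$mouse)
  cl_h <- snn_cluster(nm_h, seed = 1)
  ann_h <- annotate_clusters(nm_h, cl_h$labels, pair$truth$marker_panel)
  expect_length(setdiff(unique(unname(ann_h)), "unassigned"), 13)
  info <- unique(c(pair$truth$marker_panel$gene_id,
                   pair$truth$family_genes$gene_id))
  tc <- crossspecies_type_correlation(
    nm_h, nm_m, pair$human$cell_meta$truth_type,
    pair$mouse$cell_meta$truth_type, pair$orthologues, genes = info)
  fam <- family_grouping(tc, 4)
  truth_fam <- pair$truth$types$family[
    match(sub("^[AB]:", "", names(fam)), pair$truth$types$type)]
  expect_equal(adjusted_rand_index(fam, truth_fam), 1)
})
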