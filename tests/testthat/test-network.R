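test_that("TOM matches the hand-evaluated 3-gene formula", {
  adj <- matrix(c(0, 0.5, 0.2,
                  0.5, 0, 0.3,
                  0.2, 0.3, 0), 3, byrow = TRUE,
                dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  tom <- crossliver:::tom_from_adjacency(adj)
  expect_equal(tom["g1", "g2"], 0.56 / 1.2, tolerance = 1e-12)
  expect_equal(unname(diag(tom)), rep(1, 3))
  # centrality is the weighted degree
  expect_equal(unname(rowSums(adj)["g1"]), 0.7)
})

test_that("TOM equals the brute-force triple sum on random networks", {
  withr::with_seed(4, {
    for (p in c(5, 10)) {
      r <- matrix(runif(p * p, -1, 1), p)
      r <- (r + t(r)) / 2
      adj <- abs(r)^6
      diag(adj) <- 0
      dimnames(adj) <- list(paste0("g", 1:p), paste0("g", 1:p))
      expect_equal(crossliver:::tom_from_adjacency(adj), brute_tom(adj),
                   tolerance = 1e-12)
    }
  })
})

test_that("network construction obeys the adjacency and TOM contracts", {
  withr::with_seed(5, {
    v <- matrix(rnorm(30 * 80), 30,
                dimnames = list(sprintf("g%02d", 1:30), sprintf("c%02d", 1:80)))
    # two perfectly correlated genes, the rest independent
    v[2, ] <- v[1, ] * 2 + 3
  })
  net <- build_network(v, beta = 6)
  expect_equal(net$adjacency["g01", "g02"], 1, tolerance = 1e-10)
  expect_lt(max(net$adjacency["g01", paste0("g", sprintf("%02d", 3:30))]),
            0.05)
  expect_gt(net$tom["g01", "g02"], 0.9)
  expect_true(isSymmetric(unname(net$tom)))
  off <- net$tom[upper.tri(net$tom)]
  expect_true(all(off >= 0 & off <= 1))
  expect_equal(unname(net$centrality),
               unname(rowSums(net$adjacency)), tolerance = 1e-12)
})

test_that("centrality correlation is 1 for identical networks, ~0 for noise", {
  withr::with_seed(6, {
    v <- matrix(rnorm(20 * 50), 20,
                dimnames = list(paste0("g", 1:20), paste0("c", 1:50)))
    net <- build_network(v)
    expect_equal(centrality_correlation(net, net)$r, 1, tolerance = 1e-12)
    v2 <- matrix(rnorm(20 * 50), 20, dimnames = dimnames(v))
    rs <- replicate(10, {
      a <- build_network(matrix(rnorm(20 * 50), 20, dimnames = dimnames(v)))
      b <- build_network(matrix(rnorm(20 * 50), 20, dimnames = dimnames(v)))
      centrality_correlation(a, b)$r
    })
    expect_lt(abs(mean(rs)), 0.2)
  })
})

test_that("cross-species centralities correlate on shared family programs", {
  pair <- fix_pair_default()
  nm_h <- normalize_log(pair$human)
  nm_m <- normalize_log(pair$mouse)
  genes <- unique(c(pair$truth$marker_panel$gene_id,
                    pair$truth$family_genes$gene_id))
  bs_h <- balanced_sample(pair$human$cell_meta$truth_type, 60, seed = 1)
  bs_m <- balanced_sample(pair$mouse$cell_meta$truth_type, 60, seed = 2)
  net_h <- build_network(as.matrix(nm_h$values[, bs_h]), genes)
  net_m <- build_network(as.matrix(nm_m$values[, bs_m]), genes)
  cc <- centrality_correlation(net_h, net_m, pair$orthologues)
  expect_gt(cc$r, 0.5)
})

test_that("eigengene reduces to the standardized vector for clones", {
  x <- c(1, 4, 2, 8, 5, 7)
  v <- rbind(x, x, x)
  dimnames(v) <- list(paste0("g", 1:3), paste0("c", 1:6))
  eg <- eigengene(v, paste0("g", 1:3))
  expect_equal(unname(eg$eigengene), as.numeric(scale(x)), tolerance = 1e-10)
  expect_equal(sd(eg$eigengene), 1, tolerance = 1e-12)
})

test_that("eigengene matches a direct eigen-decomposition oracle", {
  withr::with_seed(7, {
    v <- matrix(rnorm(3 * 40), 3,
                dimnames = list(paste0("g", 1:3), paste0("c", 1:40)))
  })
  eg <- eigengene(v, paste0("g", 1:3))
  z <- t(scale(t(v)))
  es <- eigen(tcrossprod(z) / (ncol(z) - 1))
  oracle <- as.numeric(t(z) %*% es$vectors[, 1])
  oracle <- oracle / sd(oracle)
  if (cor(oracle, colMeans(z)) < 0) oracle <- -oracle
  expect_equal(unname(eg$eigengene), oracle, tolerance = 1e-8)
  # the eigengene explains at least as much variance as any other unit
  # linear combination (checked against random competitors)
  var_of <- function(w) {
    s <- as.numeric(t(z) %*% (w / sqrt(sum(w^2))))
    var(s)
  }
  best <- var_of(es$vectors[, 1])
  withr::with_seed(8, {
    for (i in 1:20) expect_lte(var_of(rnorm(3)), best + 1e-10)
  })
})

test_that("species-specificity thresholds follow the dual-cutoff rule", {
  r_a <- c(0.9, 0.9, 0.4, 0.2, 0.55)
  r_b <- c(0.2, 0.6, -0.3, 0.9, 0.04)
  got <- species_specific_genes(r_a, r_b)
  expect_equal(got, c("specific_a", "shared", "shared", "specific_b",
                      "specific_a"))
})

test_that("planted species-specific patterns are recovered from eigengenes", {
  pair <- fix_pair_default()
  nm_h <- normalize_log(pair$human)
  nm_m <- normalize_log(pair$mouse)
  sp <- pair$truth$species_specific
  mp <- pair$truth$marker_panel
  hep <- mp$gene_id[mp$type == "hepatoblast_hepatocyte"]
  bs_h <- suppressWarnings(
    balanced_sample(pair$human$cell_meta$truth_type, 100, seed = 3))
  bs_m <- suppressWarnings(
    balanced_sample(pair$mouse$cell_meta$truth_type, 100, seed = 4))
  vi_h <- knn_impute(as.matrix(nm_h$values[, bs_h]), k = 10)
  vi_m <- knn_impute(as.matrix(nm_m$values[, bs_m]), k = 10)
  eg_h <- eigengene(vi_h, hep)
  eg_m <- eigengene(vi_m, hep)
  shared <- pair$orthologues$pairs$gene_a
  cls <- species_specific_genes(eg_h$gene_correlations[shared],
                                eg_m$gene_correlations[shared])
  hh <- sp$gene_id[sp$species == "human" &
                   sp$type == "hepatoblast_hepatocyte"]
  mm <- sp$gene_id[sp$species == "mouse" &
                   sp$type == "hepatoblast_hepatocyte"]
  expect_gte(mean(cls[hh] == "specific_a"), 0.9)
  expect_gte(mean(cls[mm] == "specific_b"), 0.9)
  null_shared <- setdiff(shared, sp$gene_id)
  expect_lte(mean(cls[null_shared] != "shared"), 0.05)
})

test_that("module detection separates the planted family programs", {
  pair <- fix_pair_default()
  nm_h <- normalize_log(pair$human)
  genes <- unique(c(pair$truth$marker_panel$gene_id,
                    pair$truth$family_genes$gene_id))
  bs <- balanced_sample(pair$human$cell_meta$truth_type, 60, seed = 5)
  net <- build_network(as.matrix(nm_h$values[, bs]), genes)
  fam_of <- c(setNames(rep(pair$truth$types$family,
                           each = sum(pair$truth$marker_panel$type ==
                                      pair$truth$types$type[1])),
                       pair$truth$marker_panel$gene_id),
              setNames(pair$truth$family_genes$family,
                       pair$truth$family_genes$gene_id))
  mods <- setdiff(unique(net$modules), "0")
  covered <- vapply(mods, function(md) {
    g <- names(net$modules)[net$modules == md]
    f <- fam_of[intersect(g, names(fam_of))]
    if (!length(f)) return(NA_character_)
    tab <- table(f)
    if (max(tab) / sum(tab) > 0.5) names(which.max(tab)) else NA_character_
  }, character(1))
  expect_length(unique(stats::na.omit(covered)), 4)
})
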