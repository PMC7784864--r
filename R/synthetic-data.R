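# Shared machinery of the generators: draw NB counts for cells whose expected
# gene proportions are given column-wise, with gamma library sizes.
draw_nb_counts <- function(log_weights, lib_mean, lib_shape, phi) {
  p <- exp(log_weights)
  p <- sweep(p, 2, colSums(p), "/")
  n_cells <- ncol(p)
  lib <- rgamma(n_cells, shape = lib_shape, rate = lib_shape / lib_mean)
  mu <- sweep(p, 2, lib, "*")
  cnt <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = 1 / phi),
                nrow = nrow(mu), dimnames = dimnames(log_weights))
  cnt
}

# Deterministic, disjoint allocation of planted program genes from a pool.
take_genes <- function(pool, n, used) {
  avail <- setdiff(pool, used)
  if (length(avail) < n)
    stop("sim_config plants more program genes than available: enlarge n_genes")
  avail[seq_len(n)]
}

#' Generate a paired two-species synthetic dataset
#'
#' Simulates UMI count matrices for two species ("human" and "mouse") whose
#' planted cell types share family-level expression programs on orthologous
#' genes, so that cross-species type correlation, family grouping, network
#' centrality comparison, and species-specific gene calling all have known
#' ground truth. Counts are negative binomial with gamma-distributed per-cell
#' library sizes; type markers, family programs, batch shifts, a rare
#' early-stage hepatoblast subpopulation, and species-specific planted genes
#' are recorded in the returned truth tables.
#'
#' @param config a [sim_config()].
#' @return A list with elements `human` and `mouse` (each a
#'   [count_matrix()] whose `cell_meta` carries `species`, `stage`, `batch`,
#'   `truth_type`, `truth_family`, `truth_subpop`, `truth_doublet`),
#'   `orthologues` (an [orthologue_map()]), and `truth`: the type/family
#'   table, the marker panel (`type`, `gene_id`), family program genes,
#'   subpopulation program genes, and the planted species-specific genes.
#' @export
generate_species_pair <- function(config) {
  config <- validate_sim_config(config)
  seeds <- derive_seeds(config$seed, 4)
  panel <- liver_type_panel(config$n_cell_types, config$n_families)
  n_shared <- round(config$frac_shared_orthologues * config$n_genes)
  n_unshared <- config$n_genes - n_shared
  shared_ids <- sprintf("ORTH%04d", seq_len(n_shared))
  hs_ids <- sprintf("HSG%04d", seq_len(n_unshared))
  mm_ids <- sprintf("MMG%04d", seq_len(n_unshared))

  withr::with_seed(seeds[1], {
    base_shared <- rnorm(n_shared, mean = 0, sd = 1)
    base_hs <- rnorm(n_unshared, mean = 0, sd = 1)
    base_mm <- rnorm(n_unshared, mean = 0, sd = 1)

    # planted gene programs live on shared orthologues
    pool <- sample(shared_ids)
    used <- character()
    markers <- lapply(seq_len(config$n_cell_types), function(t) {
      g <- take_genes(pool, config$n_markers_per_type, used)
      used <<- c(used, g)
      g
    })
    fam_names <- unique(panel$family)
    fam_genes <- lapply(fam_names, function(f) {
      g <- take_genes(pool, config$n_family_genes, used)
      used <<- c(used, g)
      g
    })
    names(fam_genes) <- fam_names
    subpop_genes <- take_genes(pool, config$n_subpop_genes, used)
    used <- c(used, subpop_genes)

    # species-specific expression patterns: PAIRED orthologues that behave
    # as an extra marker of one cell type in one species only (the other
    # species leaves them at baseline), emulating genes whose orthologue
    # exists but whose regulation diverged
    n_sp <- config$n_species_specific_genes
    sp_type <- rep_len(panel$type, n_sp)
    sp_hs <- take_genes(pool, n_sp, used)
    used <- c(used, sp_hs)
    sp_mm <- take_genes(pool, n_sp, used)
    used <- c(used, sp_mm)
  })

  fam_fc <- config$marker_log_fc / 2
  type_effect <- function(species_ids, sp_ids, base_unshared) {
    gene_ids <- c(shared_ids, species_ids)
    E <- matrix(0, length(gene_ids), config$n_cell_types,
                dimnames = list(gene_ids, panel$type))
    for (t in seq_len(config$n_cell_types)) {
      E[markers[[t]], t] <- E[markers[[t]], t] + config$marker_log_fc
      f <- panel$family[t]
      E[fam_genes[[f]], t] <- E[fam_genes[[f]], t] + fam_fc
      sp_here <- sp_ids[sp_type == panel$type[t]]
      if (length(sp_here)) E[sp_here, t] <- E[sp_here, t] + config$marker_log_fc
    }
    list(gene_ids = gene_ids, E = E,
         base = c(base_shared, base_unshared))
  }

  gen_one <- function(species, sp_ids, species_ids, base_unshared, seed) {
    layout <- type_effect(species_ids, sp_ids, base_unshared)
    rare <- config$rare_subpop_fraction
    rare <- if (!is.null(names(rare))) unname(rare[species]) else unname(rare[1])
    withr::with_seed(seed, {
      n_cells <- config$n_cell_types * config$n_cells_per_type
      truth_type <- rep(panel$type, each = config$n_cells_per_type)
      truth_family <- rep(panel$family, each = config$n_cells_per_type)
      stage <- sample.int(config$n_stages, n_cells, replace = TRUE)
      batch <- sample.int(config$n_batches, n_cells, replace = TRUE)
      subpop <- truth_type == panel$type[1] & stage <= 2 &
        runif(n_cells) < rare
      batch_shift <- matrix(rnorm(length(layout$gene_ids) * config$n_batches,
                                  sd = config$batch_shift_sd),
                            nrow = length(layout$gene_ids))
      logw <- layout$base + layout$E[, truth_type] +
        batch_shift[, batch, drop = FALSE]
      if (any(subpop))
        logw[subpop_genes, subpop] <- logw[subpop_genes, subpop] +
          config$marker_log_fc
      dimnames(logw) <- list(layout$gene_ids,
                             sprintf("%s_c%05d", substr(species, 1, 2),
                                     seq_len(n_cells)))
      cnt <- draw_nb_counts(logw, config$library_size_mean,
                            config$library_size_shape, config$nb_dispersion)
    })
    meta <- data.frame(species = species, stage = stage, batch = batch,
                       truth_type = truth_type, truth_family = truth_family,
                       truth_subpop = subpop, truth_doublet = FALSE,
                       row.names = colnames(cnt), stringsAsFactors = FALSE)
    count_matrix(cnt, meta)
  }

  human <- gen_one("human", sp_hs, hs_ids, base_hs, seeds[2])
  mouse <- gen_one("mouse", sp_mm, mm_ids, base_mm, seeds[3])

  ortho <- orthologue_map(data.frame(gene_a = shared_ids, gene_b = shared_ids),
                          specific_a = hs_ids, specific_b = mm_ids)
  marker_panel <- data.frame(
    type = rep(panel$type, each = config$n_markers_per_type),
    gene_id = unlist(markers), stringsAsFactors = FALSE)
  fam_table <- data.frame(
    family = rep(names(fam_genes), lengths(fam_genes)),
    gene_id = unlist(fam_genes), stringsAsFactors = FALSE)
  sp_table <- data.frame(
    species = rep(c("human", "mouse"), each = length(sp_hs)),
    gene_id = c(sp_hs, sp_mm), type = c(sp_type, sp_type),
    family = panel$family[match(c(sp_type, sp_type), panel$type)],
    stringsAsFactors = FALSE)

  list(human = human, mouse = mouse, orthologues = ortho,
       truth = list(types = panel, marker_panel = marker_panel,
                    family_genes = fam_table, subpop_genes = subpop_genes,
                    species_specific = sp_table))
}

#' Append synthetic true doublets to a count matrix
#'
#' Adds `round(fraction * N)` doublets, each the exact count-vector sum of
#' two distinct randomly chosen parent cells, and marks them in
#' `truth_doublet`. Summing (rather than averaging) preserves UMI semantics:
#' a droplet holding two cells yields the union of their molecules.
#'
#' @param m a [count_matrix()].
#' @param fraction doublet fraction in \[0, 0.5); 0 returns `m` unchanged.
#' @param seed integer seed.
#' @return A [count_matrix()] with the doublets appended.
#' @export
spike_doublets <- function(m, fraction = NULL, seed = 1) {
  stopifnot(inherits(m, "count_matrix"))
  if (is.null(fraction)) fraction <- 0.05
  if (fraction < 0 || fraction >= 0.5)
    stop("doublet fraction must be in [0, 0.5)")
  if (fraction == 0) return(m)
  n <- ncol(m$counts)
  n_d <- round(fraction * n)
  if (n_d < 1) return(m)
  withr::with_seed(seed, {
    p1 <- sample.int(n, n_d)
    p2 <- sample.int(n, n_d)
    while (any(p1 == p2)) {
      hit <- p1 == p2
      p2[hit] <- sample.int(n, sum(hit), replace = TRUE)
    }
  })
  dbl <- m$counts[, p1, drop = FALSE] + m$counts[, p2, drop = FALSE]
  colnames(dbl) <- sprintf("dbl%05d", seq_len(n_d))
  meta_d <- m$cell_meta[p1, , drop = FALSE]
  rownames(meta_d) <- colnames(dbl)
  if (!"truth_doublet" %in% colnames(meta_d)) {
    meta_d$truth_doublet <- TRUE
    m$cell_meta$truth_doublet <- FALSE
  } else meta_d$truth_doublet <- TRUE
  if ("truth_type" %in% colnames(meta_d)) meta_d$truth_type <- "doublet"
  count_matrix(cbind(m$counts, dbl), rbind(m$cell_meta, meta_d))
}

#' Generate a synthetic differentiation trajectory
#'
#' Places hepatoblast/hepatocyte cells on a 1-D latent maturation axis that
#' increases with developmental stage, with a gradually decreasing program A
#' and increasing program B, a distinct program C expressed only in a
#' cholangiocyte branch, a gene block switching its mean level exactly
#' between stages `switch_stage_index` and `switch_stage_index + 1`, planted
#' S/G2M cycling programs whose per-stage cycling fraction declines linearly,
#' an optional rare mesenchymal subpopulation at the two earliest stages, and
#' an optional human-only bimodal program splitting late-stage cells into two
#' groups.
#'
#' @param config a [sim_config()].
#' @param species `"human"` or `"mouse"`; controls the rare-subpopulation
#'   fraction and whether the bimodal program is planted.
#' @return A [count_matrix()] whose `cell_meta` has `stage`, `truth_latent`,
#'   `truth_branch`, `truth_subpop`, `truth_phase`, `truth_group`, and whose
#'   `programs` element lists the planted gene sets (`prog_a`, `prog_b`,
#'   `prog_c`, `switch_genes`, `subpop_genes`, `s_genes`, `g2m_genes`,
#'   `vtn_genes`).
#' @export
generate_trajectory <- function(config, species = "human") {
  config <- validate_sim_config(config)
  if (config$n_stages < 3) stop("generate_trajectory needs n_stages >= 3")
  seeds <- derive_seeds(config$seed, 6)
  gene_ids <- sprintf("G%04d", seq_len(config$n_genes))
  rare <- config$rare_subpop_fraction
  rare <- if (!is.null(names(rare))) unname(rare[species]) else unname(rare[1])

  withr::with_seed(seeds[4], {
    base <- rnorm(config$n_genes, 0, 1)
    pool <- sample(gene_ids)
    used <- character()
    grab <- function(n) {
      g <- take_genes(pool, n, used); used <<- c(used, g); g
    }
    prog_a <- grab(config$n_program_genes)
    prog_b <- grab(config$n_program_genes)
    prog_c <- grab(config$n_program_genes)
    switch_genes <- grab(config$n_switch_genes)
    subpop_genes <- grab(config$n_subpop_genes)
    s_genes <- grab(config$n_cc_genes)
    g2m_genes <- grab(config$n_cc_genes)
    vtn_genes <- grab(config$n_vtn_genes)

    n_main <- config$n_stages * config$n_cells_per_stage
    stage_main <- rep(seq_len(config$n_stages), each = config$n_cells_per_stage)
    branch_stages <- seq(3, config$n_stages)
    n_branch_per <- round(config$branch_fraction * config$n_cells_per_stage)
    stage_branch <- rep(branch_stages, each = n_branch_per)
    stage <- c(stage_main, stage_branch)
    branch <- c(rep(FALSE, n_main), rep(TRUE, length(stage_branch)))
    n_cells <- length(stage)
    latent <- (stage - 1 + runif(n_cells)) / config$n_stages

    subpop <- !branch & stage <= 2 & runif(n_cells) < rare

    cyc_frac <- config$cc_fraction_start +
      (config$cc_fraction_end - config$cc_fraction_start) *
      (stage - 1) / (config$n_stages - 1)
    cycling <- runif(n_cells) < cyc_frac & !branch
    phase <- ifelse(!cycling, "G1", ifelse(runif(n_cells) < 0.5, "S", "G2M"))

    group <- rep(NA_character_, n_cells)
    if (isTRUE(config$vtn_bimodal) && species == "human") {
      late <- !branch & stage >= config$n_stages - 1
      group[late] <- ifelse(runif(sum(late)) < 0.5, "high", "low")
    }

    lfc <- config$marker_log_fc
    # cycle-signature genes are phase-specific markers: repressed outside
    # their phase, so their baseline sits below the bulk of the transcriptome
    base[match(c(s_genes, g2m_genes), gene_ids)] <-
      base[match(c(s_genes, g2m_genes), gene_ids)] - 1
    logw <- matrix(base, config$n_genes, n_cells,
                   dimnames = list(gene_ids,
                                   sprintf("%s_t%05d", substr(species, 1, 2),
                                           seq_len(n_cells))))
    # continuum and switch effects are centred (+/- half the contrast) so the
    # planted end-to-end contrast is lfc without shifting overall gene means
    logw[prog_a, ] <- logw[prog_a, ] + rep(lfc * (0.5 - latent),
                                           each = length(prog_a))
    logw[prog_b, ] <- logw[prog_b, ] + rep(lfc * (latent - 0.5),
                                           each = length(prog_b))
    if (any(branch))
      logw[prog_c, branch] <- logw[prog_c, branch] + lfc
    post <- stage > config$switch_stage_index
    logw[switch_genes, ] <- logw[switch_genes, ] +
      ifelse(rep(post, each = length(switch_genes)),
             config$switch_log_fc / 2, -config$switch_log_fc / 2)
    if (any(subpop))
      logw[subpop_genes, subpop] <- logw[subpop_genes, subpop] + lfc
    if (any(phase == "S"))
      logw[s_genes, phase == "S"] <- logw[s_genes, phase == "S"] +
        config$cc_log_fc
    if (any(phase == "G2M"))
      logw[g2m_genes, phase == "G2M"] <- logw[g2m_genes, phase == "G2M"] +
        config$cc_log_fc
    hi <- !is.na(group) & group == "high"
    if (any(hi))
      logw[vtn_genes, hi] <- logw[vtn_genes, hi] + lfc

    cnt <- draw_nb_counts(logw, config$library_size_mean,
                          config$library_size_shape, config$nb_dispersion)
  })
  meta <- data.frame(species = species, stage = stage,
                     batch = 1L,
                     truth_latent = latent, truth_branch = branch,
                     truth_subpop = subpop, truth_phase = phase,
                     truth_group = group,
                     row.names = colnames(cnt), stringsAsFactors = FALSE)
  m <- count_matrix(cnt, meta)
  m$programs <- list(prog_a = prog_a, prog_b = prog_b, prog_c = prog_c,
                     switch_genes = switch_genes, subpop_genes = subpop_genes,
                     s_genes = s_genes, g2m_genes = g2m_genes,
                     vtn_genes = vtn_genes)
  m
}

#' Generate deep plate-based (mSTRT-like) counts
#'
#' Emulates a deep-coverage plate protocol: roughly ten-fold larger library
#' sizes than the droplet generators, four developmental stage groups each
#' with its own planted program, and a configurable fraction of cells planted
#' to fail the detected-genes QC threshold (their expression is restricted to
#' fewer genes than the threshold).
#'
#' @param config a [sim_config()]; `qc_fail_fraction` and
#'   `qc_gene_threshold` control the planted QC failures.
#' @param species species label stored in the metadata.
#' @return A [count_matrix()] with `cell_meta` columns `stage` (1-4),
#'   `truth_qc_fail`, and a `programs` element listing the per-stage planted
#'   gene sets.
#' @export
generate_deep_counts <- function(config, species = "mouse") {
  config <- validate_sim_config(config)
  seeds <- derive_seeds(config$seed, 8)
  n_stage_groups <- 4
  gene_ids <- sprintf("G%04d", seq_len(config$n_genes))
  withr::with_seed(seeds[5], {
    base <- rnorm(config$n_genes, 0, 1)
    pool <- sample(gene_ids)
    used <- character()
    stage_genes <- lapply(seq_len(n_stage_groups), function(s) {
      g <- take_genes(pool, config$n_program_genes, used)
      used <<- c(used, g)
      g
    })
    n_cells <- n_stage_groups * config$n_cells_per_deep_stage
    stage <- rep(seq_len(n_stage_groups), each = config$n_cells_per_deep_stage)
    logw <- matrix(base, config$n_genes, n_cells,
                   dimnames = list(gene_ids,
                                   sprintf("%s_d%04d", substr(species, 1, 2),
                                           seq_len(n_cells))))
    for (s in seq_len(n_stage_groups))
      logw[stage_genes[[s]], stage == s] <-
        logw[stage_genes[[s]], stage == s] + config$marker_log_fc
    cnt <- draw_nb_counts(logw,
                          config$library_size_mean * config$deep_depth_multiplier,
                          config$library_size_shape, config$nb_dispersion)
    n_fail <- round(config$qc_fail_fraction * n_cells)
    qc_fail <- rep(FALSE, n_cells)
    if (n_fail > 0) {
      fail_cells <- sample.int(n_cells, n_fail)
      qc_fail[fail_cells] <- TRUE
      keep_n <- max(1L, round(config$qc_gene_threshold * 0.5))
      for (j in fail_cells) {
        keep <- sample.int(config$n_genes, keep_n)
        drop <- setdiff(seq_len(config$n_genes), keep)
        cnt[drop, j] <- 0
      }
    }
  })
  meta <- data.frame(species = species, stage = stage, batch = 1L,
                     truth_qc_fail = qc_fail,
                     row.names = colnames(cnt), stringsAsFactors = FALSE)
  m <- count_matrix(cnt, meta)
  m$programs <- list(stage_genes = stage_genes)
  m
}
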