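#' Configuration for the two-species synthetic data generator
#'
#' Collects every knob of the synthetic fetal-liver data generator. The
#' defaults encode the study design the downstream methods assume: 13 cell
#' types organized in 4 lineage families, strong (ln-FC 3) planted type
#' markers, negative-binomial counts with gamma-distributed per-cell library
#' sizes, a rare early-stage hepatoblast subpopulation (8% in human, 6% in
#' mouse), a hepatoblast-to-hepatocyte continuum with a cholangiocyte branch
#' and a stage-localized expression switch, species-specific genes, and an
#' optional human-only bimodal late-hepatocyte program.
#'
#' @param n_cell_types number of planted cell types.
#' @param n_families number of lineage families the types partition into;
#'   must not exceed `n_cell_types`.
#' @param n_genes genes per species.
#' @param frac_shared_orthologues fraction of genes with a one-to-one
#'   orthologue in the other species.
#' @param n_markers_per_type planted marker genes per cell type.
#' @param marker_log_fc natural-log fold change of planted markers (and of
#'   the other planted programs unless noted). The family-shared program uses
#'   half this effect so that `marker_log_fc = 0` switches off all planted
#'   type structure.
#' @param nb_dispersion negative-binomial dispersion phi
#'   (variance = mu + phi * mu^2).
#' @param library_size_mean,library_size_shape mean and shape of the gamma
#'   distribution of per-cell expected library sizes.
#' @param doublet_fraction default fraction used by [spike_doublets()].
#' @param n_batches,batch_shift_sd number of batches and the SD of the
#'   per-batch, per-gene log-scale shift.
#' @param rare_subpop_fraction named numeric `c(human = , mouse = )`:
#'   fraction of earliest-stage hepatoblasts in the mesenchymal-program
#'   subpopulation.
#' @param n_stages number of developmental stages.
#' @param switch_stage_index the expression switch is planted between stages
#'   `switch_stage_index` and `switch_stage_index + 1`; must be < `n_stages`.
#' @param switch_log_fc natural-log step height of the switch block.
#' @param n_species_specific_genes paired orthologues per species planted
#'   with a species-specific expression pattern: they load on one of that
#'   species' family programs while staying at baseline in the other
#'   species. (Genes without an orthologue partner are additionally present
#'   as pure background via `frac_shared_orthologues`.)
#' @param vtn_bimodal if `TRUE`, late-stage human trajectory cells split into
#'   two groups differing in a planted program (the bimodal hepatocyte
#'   heterogeneity).
#' @param seed master seed; per-operation seeds are derived from it.
#' @param n_cells_per_type cells per type in [generate_species_pair()].
#' @param n_cells_per_stage main-lineage cells per stage in
#'   [generate_trajectory()].
#' @param branch_fraction cholangiocyte-branch cells per stage as a fraction
#'   of `n_cells_per_stage` (stages 3 and later).
#' @param n_family_genes genes in each family-shared program.
#' @param n_program_genes genes in each trajectory program (decreasing A,
#'   increasing B, branch-only C).
#' @param n_switch_genes genes in the planted switch block.
#' @param n_subpop_genes genes in the rare-subpopulation mesenchymal program.
#' @param n_cc_genes genes in each planted cell-cycle signature (S and G2M);
#'   the default matches the size of the canonical S/G2M phase gene lists
#'   (43 and 54 genes).
#' @param cc_log_fc natural-log fold change of the cycling programs.
#' @param cc_fraction_start,cc_fraction_end fraction of cycling cells at the
#'   first and last stages (linearly interpolated in between).
#' @param n_vtn_genes genes in the bimodal late-stage program.
#' @param n_cells_per_deep_stage cells per stage group in
#'   [generate_deep_counts()].
#' @param deep_depth_multiplier library-size multiplier for the deep
#'   (plate-based) generator.
#' @param qc_fail_fraction fraction of deep cells planted to fail the
#'   detected-genes QC threshold.
#' @param qc_gene_threshold detected-gene QC threshold used when planting
#'   failing cells.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_cell_types = 13,
                       n_families = 4,
                       n_genes = 2000,
                       frac_shared_orthologues = 0.9,
                       n_markers_per_type = 20,
                       marker_log_fc = 3,
                       nb_dispersion = 0.3,
                       library_size_mean = 2000,
                       library_size_shape = 10,
                       doublet_fraction = 0.05,
                       n_batches = 2,
                       batch_shift_sd = 0.15,
                       rare_subpop_fraction = c(human = 0.08, mouse = 0.06),
                       n_stages = 6,
                       switch_stage_index = 4,
                       switch_log_fc = 1.5,
                       n_species_specific_genes = 100,
                       vtn_bimodal = TRUE,
                       seed = 1,
                       n_cells_per_type = 80,
                       n_cells_per_stage = 250,
                       branch_fraction = 0.10,
                       n_family_genes = 40,
                       n_program_genes = 40,
                       n_switch_genes = 30,
                       n_subpop_genes = 30,
                       n_cc_genes = 40,
                       cc_log_fc = 2,
                       cc_fraction_start = 0.5,
                       cc_fraction_end = 0.1,
                       n_vtn_genes = 25,
                       n_cells_per_deep_stage = 75,
                       deep_depth_multiplier = 10,
                       qc_fail_fraction = 0.1,
                       qc_gene_threshold = 800) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk_frac <- function(name) {
    v <- cfg[[name]]
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
      stop(sprintf("invalid sim_config field '%s': must be in [0, 1]", name))
  }
  for (f in c("frac_shared_orthologues", "doublet_fraction",
              "rare_subpop_fraction", "branch_fraction",
              "cc_fraction_start", "cc_fraction_end", "qc_fail_fraction"))
    chk_frac(f)
  chk_pos <- function(name) {
    v <- cfg[[name]]
    if (!is.finite(v) || v <= 0)
      stop(sprintf("invalid sim_config field '%s': must be positive", name))
  }
  for (f in c("nb_dispersion", "library_size_mean", "library_size_shape"))
    chk_pos(f)
  if (cfg$marker_log_fc < 0)
    stop("invalid sim_config field 'marker_log_fc': must be >= 0")
  if (cfg$n_families > cfg$n_cell_types)
    stop("invalid sim_config field 'n_families': exceeds n_cell_types")
  if (cfg$switch_stage_index >= cfg$n_stages)
    stop("invalid sim_config field 'switch_stage_index': must be < n_stages")
  if (length(cfg$rare_subpop_fraction) == 1 &&
      is.null(names(cfg$rare_subpop_fraction)))
    cfg$rare_subpop_fraction <- c(human = unname(cfg$rare_subpop_fraction),
                                  mouse = unname(cfg$rare_subpop_fraction))
  cfg
}

# Names of the 13 fetal-liver cell types and their 4 lineage families; when
# n_cell_types differs from 13 the generator falls back to generic names with
# near-equal contiguous family blocks.
liver_type_panel <- function(n_types, n_families) {
  if (n_types == 13 && n_families == 4) {
    types <- c("hepatoblast_hepatocyte", "cholangiocyte",
               "erythroid_progenitor", "erythroblast", "early_erythrocyte",
               "primitive_erythrocyte", "HSPC", "myeloid_lymphoid_mk",
               "kupffer_cell", "hepatic_stellate_cell",
               "septum_transversum_cell", "mesothelial_cell",
               "endothelial_cell")
    fams <- c("endoderm", "endoderm",
              "erythroid", "erythroid", "erythroid", "erythroid",
              "non_erythroid_hematopoietic", "non_erythroid_hematopoietic",
              "non_erythroid_hematopoietic",
              "mesoderm_non_hematopoietic", "mesoderm_non_hematopoietic",
              "mesoderm_non_hematopoietic", "mesoderm_non_hematopoietic")
  } else {
    types <- sprintf("type%02d", seq_len(n_types))
    fam_idx <- sort(rep_len(seq_len(n_families), n_types))
    fams <- sprintf("family%d", fam_idx)
  }
  data.frame(type = types, family = fams, stringsAsFactors = FALSE)
}
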