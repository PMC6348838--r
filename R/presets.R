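# Ratio of the PD-1 marginal to the TIGIT marginal implied by the encoded
# conditionals P(PD-1+|TIGIT+) = 0.78 and P(TIGIT+|PD-1+) = 0.96: keeping
# p(PD-1) = k * p(TIGIT) everywhere makes the joint exactly consistent.
# The conditionals are encoded above the reported bounds (>0.70, >0.90)
# because gating through max-of-negative-controls thresholds dilutes the
# measured conditionals with a ~1/(m+1) false-positive leak.
.k_pd1 <- 0.78 / 0.96

# Encoded TIGIT marginal positivity per cell type (tonsil baseline; the
# compartment overrides below reshape CD4 between follicle and
# interfollicular area).
.tigit_marginals <- c(CD4_T = 0.20, CD8_T = 0.53, FOXP3_Treg = 0.72,
                      CD3_T = 0.35, CD56_NK = 0.35,
                      CD20_B = 0, CD11c_DC = 0, CD68_Mac = 0, other = 0)

# Lineage markers truly expressed by each cell type (positivity fraction).
.lineage_expression <- list(
  CD20_B     = c(CD20 = 0.98),
  CD3_T      = c(CD3 = 0.98),
  CD4_T      = c(CD3 = 0.98, CD4 = 0.98),
  CD8_T      = c(CD3 = 0.98, CD8 = 0.98),
  FOXP3_Treg = c(CD3 = 0.98, CD4 = 0.90, FOXP3 = 0.95),
  CD56_NK    = c(CD56 = 0.95),
  CD11c_DC   = c(CD11c = 0.95),
  CD68_Mac   = c(CD68 = 0.95),
  other      = c()
)

# Build the full (cell type x marker) mixture table shared by all presets.
# Lineage positives are bright (log-mean 4.2) and checkpoints slightly
# dimmer (3.8) over a common background (log-mean 1.6, sd 0.35); the
# positive/background separation is ~5 background sds so gating recovers
# the encoded marginals to within a fraction of a percent.
default_mixtures <- function(panel = marker_panel()) {
  types <- names(.lineage_expression)
  mixtures <- lapply(types, function(ct) {
    mx <- lapply(panel$markers, function(mk) {
      if (mk %in% panel$checkpoint_markers) {
        p <- unname(.tigit_marginals[[ct]])
        if (mk == "PD-1") p <- p * .k_pd1
        if (ct == "CD56_NK" && mk == "PD-1") p <- 0.35 * 0.5 / 0.8
        intensity_mixture(pos_fraction = p, pos_log_mean = 3.8, pos_log_sd = 0.45)
      } else {
        p <- unname(.lineage_expression[[ct]][mk])
        intensity_mixture(pos_fraction = if (is.null(p) || is.na(p)) 0 else p,
                          pos_log_mean = 4.2, pos_log_sd = 0.4)
      }
    })
    names(mx) <- panel$markers
    mx
  })
  names(mixtures) <- types
  mixtures
}

default_copositivity <- function() {
  t_like <- c(p_pd1_given_tigit = 0.78, p_tigit_given_pd1 = 0.96)
  none <- c(p_pd1_given_tigit = 0, p_tigit_given_pd1 = 0)
  list(CD4_T = t_like, CD8_T = t_like, FOXP3_Treg = t_like, CD3_T = t_like,
       CD56_NK = c(p_pd1_given_tigit = 0.5, p_tigit_given_pd1 = 0.8),
       CD20_B = none, CD11c_DC = none, CD68_Mac = none, other = none)
}

# Compartment-specific CD4 positivity overrides (fraction changes between
# follicle and interfollicular area are encoded on the fraction, not the
# intensity). PD-1 kept proportional so the copula stays consistent.
.cd4_override <- function(p_tigit) {
  list(CD4_T = c("TIGIT" = p_tigit, "PD-1" = p_tigit * .k_pd1))
}

# Follicular CD4 (Tfh-like): near-saturated TIGIT (97%) and PD-1 (93%)
# with 92% double positivity — the cohort-level conditionals are
# infeasible at these marginals (Frechet), and follicular T helper cells
# co-express both receptors almost completely.
.cd4_follicle_pos <- list(CD4_T = c("TIGIT" = 0.97, "PD-1" = 0.93))
.cd4_follicle_cop <- list(CD4_T = c(p_pd1_given_tigit = 0.92 / 0.97,
                                    p_tigit_given_pd1 = 0.92 / 0.93))

tonsil_compartments <- function() {
  list(
    compartment_spec("Ia", 4000,
      c(CD20_B = 0.20, CD4_T = 0.38, CD8_T = 0.20, FOXP3_Treg = 0.06,
        CD3_T = 0.05, CD56_NK = 0.03, CD11c_DC = 0.03, CD68_Mac = 0.03,
        other = 0.02),
      checkpoint_gradient = c("TIGIT" = 1.0, "PD-1" = 1.0),
      pos_fraction_overrides = .cd4_override(0.47)),
    compartment_spec("Mz", 2500,
      c(CD20_B = 0.55, CD4_T = 0.08, CD8_T = 0.08, FOXP3_Treg = 0.05,
        CD3_T = 0.03, CD56_NK = 0.02, CD11c_DC = 0.04, CD68_Mac = 0.04,
        other = 0.11),
      checkpoint_gradient = c("TIGIT" = 4.5, "PD-1" = 4.2)),
    compartment_spec("Gcp", 1500,
      c(CD20_B = 0.52, CD4_T = 0.06, CD8_T = 0.07, FOXP3_Treg = 0.06,
        CD3_T = 0.03, CD56_NK = 0.01, CD11c_DC = 0.04, CD68_Mac = 0.04,
        other = 0.17),
      checkpoint_gradient = c("TIGIT" = 8.0, "PD-1" = 8.8),
      pos_fraction_overrides = .cd4_follicle_pos,
      copositivity_overrides = .cd4_follicle_cop),
    compartment_spec("Gcc", 2000,
      c(CD20_B = 0.65, CD4_T = 0.03, CD8_T = 0.05, FOXP3_Treg = 0.05,
        CD3_T = 0.02, CD56_NK = 0.01, CD11c_DC = 0.03, CD68_Mac = 0.03,
        other = 0.13),
      checkpoint_gradient = c("TIGIT" = 9.0, "PD-1" = 10.0),
      pos_fraction_overrides = .cd4_follicle_pos,
      copositivity_overrides = .cd4_follicle_cop)
  )
}

#' Named scenario presets for the synthetic cohort generator
#'
#' Returns a fully resolved [generator_config()] whose encoded marginals and
#' gradients mirror the study scenarios qualitatively:
#'
#' * `tonsil` — four concentric lymph-follicle compartments (Ia, Mz, Gcp,
#'   Gcc) with a monotone TIGIT/PD-1 intensity gradient from the
#'   interfollicular area into the germinal centre, interfollicular CD4
#'   positivity ~47% vs >95% in the follicle, and a reference tonsil tissue
#'   for normalization. The encoded pooled marginals are TIGIT+ in ~52% of
#'   CD3+ cells and 47%/53%/72% of CD4/CD8/FOXP3 T cells; >70% of TIGIT+
#'   cells are PD-1+ and >90% of PD-1+ cells TIGIT+.
#' * `hashimoto` — lymph follicle and interfollicular compartments whose
#'   checkpoint intensity is 2.5-fold the matched tonsil compartments.
#' * `sarcoidosis` — granuloma vs intergranuloma; TIGIT brighter in the
#'   intergranulomatous area and TIGIT:PD-1 ratio > 1.
#' * `lichen_sclerosus`, `igg4_pancreatitis`, `rheumatoid_arthritis` —
#'   dense lymphocytic infiltration vs sparse stroma, PD-1 upregulated
#'   relative to TIGIT (ratio < 1).
#' * `tumour_margin_centre` — invasive margin vs tumour centre with higher
#'   CD8+TIGIT+ abundance and brighter checkpoints at the margin.
#' * `tma_spot_survey` — replicate 0.6 mm tumour spots for density counting.
#'
#' @param name Preset name (see above).
#' @param seed Integer seed stored in the returned config.
#' @return A [generator_config()].
#' @examples
#' cfg <- make_preset("tonsil")
#' vapply(cfg$compartments, function(x) x$name, character(1))
#' @export
make_preset <- function(name, seed = 1) {
  valid <- c("tonsil", "hashimoto", "sarcoidosis", "lichen_sclerosus",
             "igg4_pancreatitis", "rheumatoid_arthritis",
             "tumour_margin_centre", "tma_spot_survey")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid))
    mfi_stop("mfi_lookup_error", "unknown preset '%s'; valid presets: %s",
             as.character(name)[1], paste(valid, collapse = ", "))
  panel <- marker_panel()
  mixtures <- default_mixtures(panel)
  copos <- default_copositivity()
  ref <- tonsil_compartments()

  infl_props <- c(CD20_B = 0.20, CD4_T = 0.28, CD8_T = 0.18, FOXP3_Treg = 0.06,
                  CD3_T = 0.05, CD56_NK = 0.02, CD11c_DC = 0.05,
                  CD68_Mac = 0.08, other = 0.08)
  sparse_props <- c(CD20_B = 0.08, CD4_T = 0.15, CD8_T = 0.10,
                    FOXP3_Treg = 0.03, CD3_T = 0.04, CD56_NK = 0.02,
                    CD11c_DC = 0.06, CD68_Mac = 0.15, other = 0.37)
  # dense infiltrate: PD-1 upregulated beyond TIGIT (TIGIT:PD-1 < 1)
  dense_vs_sparse <- function(n_dense, n_sparse) list(
    compartment_spec("lymphocytic_infiltration", n_dense, infl_props,
                     checkpoint_gradient = c("TIGIT" = 2.0, "PD-1" = 3.0)),
    compartment_spec("sparse_stroma", n_sparse, sparse_props,
                     checkpoint_gradient = c("TIGIT" = 1.0, "PD-1" = 1.2)))

  switch(name,
    tonsil = generator_config(
      panel, tonsil_compartments(), mixtures, copos,
      spot_diameter_mm = 4, seed = seed, reference_included = TRUE,
      reference_compartments = ref),
    hashimoto = generator_config(
      panel,
      list(
        compartment_spec("lymph_follicle", 2500,
          c(CD20_B = 0.55, CD4_T = 0.10, CD8_T = 0.07, FOXP3_Treg = 0.06,
            CD3_T = 0.03, CD56_NK = 0.01, CD11c_DC = 0.04, CD68_Mac = 0.04,
            other = 0.10),
          # 2.5x the matched tonsil compartment (Gcc: 9.0 / 10.0)
          checkpoint_gradient = c("TIGIT" = 22.5, "PD-1" = 25.0),
          pos_fraction_overrides = .cd4_follicle_pos,
          copositivity_overrides = .cd4_follicle_cop),
        compartment_spec("interfollicular", 3500,
          c(CD20_B = 0.18, CD4_T = 0.35, CD8_T = 0.20, FOXP3_Treg = 0.06,
            CD3_T = 0.05, CD56_NK = 0.03, CD11c_DC = 0.04, CD68_Mac = 0.04,
            other = 0.05),
          checkpoint_gradient = c("TIGIT" = 2.5, "PD-1" = 2.5),
          pos_fraction_overrides = .cd4_override(0.47))),
      mixtures, copos, spot_diameter_mm = 4, seed = seed,
      reference_included = TRUE, reference_compartments = ref,
      n_test_tissues = 2),
    sarcoidosis = generator_config(
      panel,
      list(
        compartment_spec("granuloma", 2000,
          c(CD68_Mac = 0.30, CD11c_DC = 0.10, CD4_T = 0.25, CD8_T = 0.10,
            FOXP3_Treg = 0.05, CD3_T = 0.05, CD20_B = 0.05, CD56_NK = 0.03,
            other = 0.07),
          checkpoint_gradient = c("TIGIT" = 1.5, "PD-1" = 1.2)),
        compartment_spec("intergranuloma", 3000,
          c(CD4_T = 0.30, CD8_T = 0.15, FOXP3_Treg = 0.06, CD3_T = 0.05,
            CD20_B = 0.15, CD56_NK = 0.03, CD11c_DC = 0.05, CD68_Mac = 0.08,
            other = 0.13),
          checkpoint_gradient = c("TIGIT" = 3.0, "PD-1" = 1.8))),
      mixtures, copos, spot_diameter_mm = 4, seed = seed,
      reference_included = TRUE, reference_compartments = ref,
      n_test_tissues = 2),
    lichen_sclerosus = generator_config(
      panel, dense_vs_sparse(3000, 1000), mixtures, copos,
      spot_diameter_mm = 4, seed = seed, reference_included = TRUE,
      reference_compartments = ref, n_test_tissues = 2),
    igg4_pancreatitis = generator_config(
      panel, dense_vs_sparse(3200, 900), mixtures, copos,
      spot_diameter_mm = 4, seed = seed, reference_included = TRUE,
      reference_compartments = ref, n_test_tissues = 2),
    rheumatoid_arthritis = generator_config(
      panel, dense_vs_sparse(2800, 1100), mixtures, copos,
      spot_diameter_mm = 4, seed = seed, reference_included = TRUE,
      reference_compartments = ref, n_test_tissues = 2),
    tumour_margin_centre = generator_config(
      panel,
      list(
        compartment_spec("invasive_margin", 3000,
          c(CD8_T = 0.30, CD4_T = 0.20, FOXP3_Treg = 0.05, CD3_T = 0.04,
            CD20_B = 0.10, CD56_NK = 0.03, CD11c_DC = 0.05, CD68_Mac = 0.10,
            other = 0.13),
          checkpoint_gradient = c("TIGIT" = 4.0, "PD-1" = 4.5)),
        compartment_spec("tumour_centre", 1500,
          c(CD8_T = 0.08, CD4_T = 0.08, FOXP3_Treg = 0.02, CD3_T = 0.02,
            CD20_B = 0.03, CD56_NK = 0.02, CD11c_DC = 0.04, CD68_Mac = 0.12,
            other = 0.59),
          checkpoint_gradient = c("TIGIT" = 1.2, "PD-1" = 1.4))),
      mixtures, copos, spot_diameter_mm = 4, seed = seed,
      reference_included = TRUE, reference_compartments = ref,
      n_test_tissues = 2),
    tma_spot_survey = generator_config(
      panel,
      list(compartment_spec("tumour", 900,
        c(CD8_T = 0.12, CD4_T = 0.10, FOXP3_Treg = 0.03, CD3_T = 0.03,
          CD20_B = 0.05, CD56_NK = 0.02, CD11c_DC = 0.04, CD68_Mac = 0.10,
          other = 0.51),
        checkpoint_gradient = c("TIGIT" = 2.0, "PD-1" = 2.2))),
      mixtures, copos, spot_diameter_mm = 0.6, seed = seed,
      reference_included = FALSE, n_test_tissues = 8)
  )
}
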