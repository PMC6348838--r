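# Small, fast synthetic configurations used across the unit tests.
# Built entirely through the public constructors.

tiny_mixtures <- function(panel = marker_panel(),
                          p_tigit_cd4 = 0.5, c1 = 0.78, c2 = 0.96) {
  expr <- list(
    CD20_B = c(CD20 = 0.98),
    CD4_T  = c(CD3 = 0.98, CD4 = 0.98),
    other  = c()
  )
  mixtures <- lapply(names(expr), function(ct) {
    mx <- lapply(panel$markers, function(mk) {
      if (mk == "TIGIT") {
        p <- if (ct == "CD4_T") p_tigit_cd4 else 0
        intensity_mixture(p, pos_log_mean = 3.8, pos_log_sd = 0.45)
      } else if (mk == "PD-1") {
        p <- if (ct == "CD4_T") p_tigit_cd4 * c1 / c2 else 0
        intensity_mixture(p, pos_log_mean = 3.8, pos_log_sd = 0.45)
      } else {
        p <- unname(expr[[ct]][mk])
        intensity_mixture(if (is.null(p) || is.na(p)) 0 else p,
                          pos_log_mean = 4.2, pos_log_sd = 0.4)
      }
    })
    names(mx) <- panel$markers
    mx
  })
  names(mixtures) <- names(expr)
  mixtures
}

tiny_copositivity <- function(c1 = 0.78, c2 = 0.96) {
  none <- c(p_pd1_given_tigit = 0, p_tigit_given_pd1 = 0)
  list(CD4_T = c(p_pd1_given_tigit = c1, p_tigit_given_pd1 = c2),
       CD20_B = none, other = none)
}

tiny_config <- function(n_cells = 1000, seed = 7, p_tigit_cd4 = 0.5,
                        c1 = 0.78, c2 = 0.96, reference_included = FALSE,
                        spot_diameter_mm = 2,
                        proportions = c(CD20_B = 0.4, CD4_T = 0.4, other = 0.2)) {
  generator_config(
    panel = marker_panel(),
    compartments = list(compartment_spec("spotA", n_cells, proportions)),
    mixtures = tiny_mixtures(p_tigit_cd4 = p_tigit_cd4, c1 = c1, c2 = c2),
    copositivity = tiny_copositivity(c1, c2),
    spot_diameter_mm = spot_diameter_mm, seed = seed,
    reference_included = reference_included,
    n_cells_range = c(1, 6000))
}

# Minimal phenotype row builder for gating/quantification unit tests.
blank_pheno <- function(n, panel = marker_panel()) {
  df <- data.frame(cell_id = sprintf("c%03d", seq_len(n)),
                   tissue_id = "t1", tissue_role = "test",
                   compartment = "A", x_um = 0, y_um = 0,
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (mk in panel$markers) df[[mk]] <- rep(FALSE, n)
  df
}
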