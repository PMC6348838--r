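#' Two-component lognormal intensity mixture
#'
#' Raw fluorescence intensities of one marker in one cell type are modelled
#' as a mixture of a negative (background / nonspecific) and a positive
#' (expressing) lognormal component. Intensities are in arbitrary units:
#' only ratios and reference-normalized quantities are meaningful.
#'
#' @param pos_fraction Probability that a cell of this type truly expresses
#'   the marker (the encoded marginal positivity).
#' @param pos_log_mean,pos_log_sd Log-scale mean and sd of the positive
#'   component.
#' @param neg_log_mean,neg_log_sd Log-scale mean and sd of the background
#'   component.
#' @return An object of class `intensity_mixture`.
#' @export
intensity_mixture <- function(pos_fraction,
                              pos_log_mean = 3.8, pos_log_sd = 0.45,
                              neg_log_mean = 1.6, neg_log_sd = 0.35) {
  assert_scalar_number(pos_fraction, "pos_fraction", 0)
  if (pos_fraction > 1)
    mfi_stop("mfi_config_error", "pos_fraction must be in [0, 1], got %s",
             format(pos_fraction))
  assert_scalar_number(pos_log_sd, "pos_log_sd", 0, strict_min = TRUE)
  assert_scalar_number(neg_log_sd, "neg_log_sd", 0, strict_min = TRUE)
  if (pos_log_mean <= neg_log_mean)
    mfi_stop("mfi_config_error",
             "positive component must be brighter than background (pos_log_mean %s <= neg_log_mean %s)",
             format(pos_log_mean), format(neg_log_mean))
  structure(list(neg_log_mean = neg_log_mean, neg_log_sd = neg_log_sd,
                 pos_log_mean = pos_log_mean, pos_log_sd = pos_log_sd,
                 pos_fraction = pos_fraction),
            class = "intensity_mixture")
}

#' Specify one tissue compartment of a synthetic cohort
#'
#' @param name Compartment label (e.g. `"Ia"`, `"Mz"`, `"Gcp"`, `"Gcc"`, or
#'   scenario labels such as `"granuloma"`, `"invasive_margin"`).
#' @param n_cells Number of cells to generate in the compartment.
#' @param cell_type_proportions Named numeric vector of cell-type
#'   proportions; must sum to 1.
#' @param checkpoint_gradient Named numeric vector, checkpoint marker ->
#'   multiplicative factor applied to that marker's positive-component
#'   log-mean in this compartment. Encodes compartment expression gradients.
#' @param pos_fraction_overrides Named list: cell type -> named numeric of
#'   marker -> positivity fraction overriding the cohort-level mixture's
#'   `pos_fraction` in this compartment. Used where positivity *fractions*
#'   (not just intensities) differ between compartments.
#' @param copositivity_overrides Named list: cell type -> numeric vector
#'   with `p_pd1_given_tigit` / `p_tigit_given_pd1` overriding the
#'   cohort-level conditionals in this compartment. Needed when a
#'   compartment's marginals are so high that the cohort conditionals
#'   would violate the Frechet bounds (e.g. near-saturated follicular CD4).
#' @return An object of class `compartment_spec`.
#' @export
compartment_spec <- function(name, n_cells, cell_type_proportions,
                             checkpoint_gradient = c("TIGIT" = 1, "PD-1" = 1),
                             pos_fraction_overrides = list(),
                             copositivity_overrides = list()) {
  stopifnot(is.character(name), length(name) == 1L)
  assert_scalar_number(n_cells, "n_cells", 1)
  p <- cell_type_proportions
  if (is.null(names(p)) || any(!nzchar(names(p))))
    mfi_stop("mfi_config_error", "cell_type_proportions must be a named vector")
  if (any(p < 0))
    mfi_stop("mfi_config_error", "cell_type_proportions must be non-negative")
  if (abs(sum(p) - 1) > 1e-9)
    mfi_stop("mfi_config_error",
             "cell_type_proportions for compartment '%s' must sum to 1 (got %.12f)",
             name, sum(p))
  if (any(checkpoint_gradient <= 0))
    mfi_stop("mfi_config_error", "checkpoint_gradient factors must be positive")
  structure(list(name = name, n_cells = as.integer(n_cells),
                 cell_type_proportions = p,
                 checkpoint_gradient = checkpoint_gradient,
                 pos_fraction_overrides = pos_fraction_overrides,
                 copositivity_overrides = copositivity_overrides),
            class = "compartment_spec")
}

#' Full parameterization of a synthetic cohort
#'
#' Bundles the marker panel, compartment specifications, per (cell type,
#' marker) intensity mixtures, the TIGIT/PD-1 co-positivity structure, spot
#' geometry and the random seed. Validates all cross-field invariants, in
#' particular that the configured conditional co-positivity probabilities
#' are jointly consistent with the (compartment-effective) marginal
#' positive fractions of the two checkpoint markers.
#'
#' @param panel A [marker_panel()].
#' @param compartments List of [compartment_spec()] objects.
#' @param mixtures Named list: cell type -> named list of marker ->
#'   [intensity_mixture()]. Every cell type appearing in any compartment's
#'   proportions must have a mixture for every panel marker.
#' @param copositivity Named list: cell type -> numeric vector with elements
#'   `p_pd1_given_tigit` (P(PD-1+ | TIGIT+)) and `p_tigit_given_pd1`
#'   (P(TIGIT+ | PD-1+)).
#' @param spot_diameter_mm Diameter of the circular tissue spot in mm; cell
#'   positions are drawn uniformly within this disc.
#' @param seed Integer seed; a fixed seed yields a byte-identical cell table.
#' @param reference_included If `TRUE`, an additional reference tissue
#'   (`tissue_role == "reference"`) is generated, by default a tonsil-like
#'   tissue built from `reference_compartments`.
#' @param reference_compartments List of [compartment_spec()] for the
#'   reference tissue; defaults to `compartments`.
#' @param n_test_tissues Number of replicate test tissues (e.g. TMA spots).
#' @param n_cells_range Allowed range for each compartment's `n_cells`;
#'   the shipped presets keep compartments within the default 800-6000.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(panel = marker_panel(), compartments, mixtures,
                             copositivity, spot_diameter_mm = 4, seed = 1,
                             reference_included = FALSE,
                             reference_compartments = NULL,
                             n_test_tissues = 1,
                             n_cells_range = c(800, 6000)) {
  stopifnot(inherits(panel, "marker_panel"))
  if (length(panel$checkpoint_markers) != 2L ||
      !setequal(panel$checkpoint_markers, c("TIGIT", "PD-1")))
    mfi_stop("mfi_config_error",
             "the generator's checkpoint co-positivity model requires the checkpoint markers to be exactly TIGIT and PD-1")
  assert_scalar_number(spot_diameter_mm, "spot_diameter_mm", 0, strict_min = TRUE)
  assert_scalar_number(n_test_tissues, "n_test_tissues", 1)
  cfg <- structure(list(panel = panel, compartments = compartments,
                        mixtures = mixtures, copositivity = copositivity,
                        spot_diameter_mm = spot_diameter_mm,
                        seed = as.integer(seed),
                        reference_included = isTRUE(reference_included),
                        reference_compartments =
                          reference_compartments %||% compartments,
                        n_test_tissues = as.integer(n_test_tissues),
                        n_cells_range = n_cells_range),
                   class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  all_comps <- c(cfg$compartments,
                 if (cfg$reference_included) cfg$reference_compartments)
  nm <- vapply(cfg$compartments, function(x) x$name, character(1))
  if (anyDuplicated(nm))
    mfi_stop("mfi_config_error", "compartment names must be unique")
  for (comp in all_comps) {
    if (!inherits(comp, "compartment_spec"))
      mfi_stop("mfi_config_error", "compartments must be compartment_spec objects")
    if (comp$n_cells < cfg$n_cells_range[1] || comp$n_cells > cfg$n_cells_range[2])
      mfi_stop("mfi_config_error",
               "compartment '%s' has n_cells = %d outside the configured range [%d, %d]",
               comp$name, comp$n_cells, cfg$n_cells_range[1], cfg$n_cells_range[2])
    for (ct in names(comp$cell_type_proportions)) {
      mx <- cfg$mixtures[[ct]]
      if (is.null(mx))
        mfi_stop("mfi_config_error", "no mixtures configured for cell type '%s'", ct)
      missing <- setdiff(cfg$panel$markers, names(mx))
      if (length(missing))
        mfi_stop("mfi_config_error", "cell type '%s' lacks a mixture for marker(s): %s",
                 ct, paste(missing, collapse = ", "))
      # checkpoint joint/marginal consistency at this compartment's
      # effective marginals
      pT <- effective_pos_fraction(cfg, comp, ct, "TIGIT")
      pP <- effective_pos_fraction(cfg, comp, ct, "PD-1")
      cp <- effective_copositivity(cfg, comp, ct)
      if (is.null(cp))
        mfi_stop("mfi_config_error", "no co-positivity configured for cell type '%s'", ct)
      c1 <- unname(cp[["p_pd1_given_tigit"]])
      c2 <- unname(cp[["p_tigit_given_pd1"]])
      if (any(c(c1, c2) < 0) || any(c(c1, c2) > 1))
        mfi_stop("mfi_config_error",
                 "conditional co-positivity probabilities for '%s' must be in [0, 1]", ct)
      j1 <- c1 * pT
      j2 <- c2 * pP
      if (abs(j1 - j2) > 1e-6)
        mfi_stop("mfi_config_error",
                 "inconsistent co-positivity for cell type '%s' in compartment '%s': P(PD-1+|TIGIT+)*P(TIGIT+) = %.6f but P(TIGIT+|PD-1+)*P(PD-1+) = %.6f",
                 ct, comp$name, j1, j2)
      if (j1 > min(pT, pP) + 1e-9 || j1 < max(0, pT + pP - 1) - 1e-9)
        mfi_stop("mfi_config_error",
                 "joint TIGIT/PD-1 positivity for cell type '%s' in compartment '%s' violates the Frechet bounds",
                 ct, comp$name)
    }
  }
  invisible(cfg)
}

# Effective conditional co-positivity for `cell_type` in `comp`.
effective_copositivity <- function(cfg, comp, cell_type) {
  comp$copositivity_overrides[[cell_type]] %||% cfg$copositivity[[cell_type]]
}

# Effective positive fraction of `marker` for `cell_type` in `comp`:
# compartment override if present, else the cohort mixture's pos_fraction.
effective_pos_fraction <- function(cfg, comp, cell_type, marker) {
  ov <- comp$pos_fraction_overrides[[cell_type]]
  if (!is.null(ov) && marker %in% names(ov)) return(unname(ov[[marker]]))
  cfg$mixtures[[cell_type]][[marker]]$pos_fraction
}

# Effective positive-component log-mean. The compartment gradient factor is
# a fold-change on the positive component's intensity scale (additive in
# log), so a factor of 2 means "positive cells twice as bright".
effective_pos_log_mean <- function(cfg, comp, cell_type, marker) {
  mu <- cfg$mixtures[[cell_type]][[marker]]$pos_log_mean
  g <- comp$checkpoint_gradient
  if (marker %in% names(g)) mu <- mu + log(unname(g[[marker]]))
  mu
}

# --- Gaussian copula machinery for the TIGIT/PD-1 joint draw ---------------

# P(Z1 <= q1, Z2 <= q2) for standard bivariate normal with correlation rho.
binorm_cdf <- function(q1, q2, rho) {
  if (abs(rho) < 1e-12) return(stats::pnorm(q1) * stats::pnorm(q2))
  s <- sqrt(1 - rho^2)
  stats::integrate(function(z) stats::dnorm(z) * stats::pnorm((q2 - rho * z) / s),
                   lower = -Inf, upper = q1,
                   rel.tol = 1e-11, abs.tol = 1e-13)$value
}

.rho_cache <- new.env(parent = emptyenv())

# Solve for the latent correlation giving joint probability p11 at marginals
# (pT, pP). Exact at the configured conditionals by construction.
solve_copula_rho <- function(pT, pP, p11) {
  key <- sprintf("%.12g|%.12g|%.12g", pT, pP, p11)
  if (!is.null(.rho_cache[[key]])) return(.rho_cache[[key]])
  q1 <- stats::qnorm(pT); q2 <- stats::qnorm(pP)
  if (abs(p11 - pT * pP) < 1e-12) {
    rho <- 0
  } else {
    f <- function(r) binorm_cdf(q1, q2, r) - p11
    rho <- stats::uniroot(f, lower = -0.9995, upper = 0.9995, tol = 1e-10)$root
  }
  .rho_cache[[key]] <- rho
  rho
}

# --- Cell generation -------------------------------------------------------

#' Generate a synthetic per-cell intensity table
#'
#' Draws one row per cell. Within each compartment, cell types follow the
#' configured proportions (multinomial); each marker intensity is drawn from
#' the cell type's lognormal mixture, the positive component being used iff
#' the cell is simulated marker-positive. TIGIT and PD-1 positivity
#' indicators are coupled through a Gaussian copula whose correlation is
#' solved from the configured conditional probabilities, so the encoded
#' P(PD-1+ | TIGIT+) and P(TIGIT+ | PD-1+) hold in expectation. Positions
#' are uniform within the circular spot.
#'
#' Ground truth (the simulated cell type and per-marker positivity) is kept
#' in a sidecar table so the analysis path cannot consume it accidentally.
#'
#' @param config A [generator_config()] (or [make_preset()] result).
#' @return An object of class `sim_cohort`: list with `cells` (the analysis
#'   table: cell_id, tissue_id, tissue_role, compartment, x_um, y_um, one
#'   raw-intensity column per marker), `truth` (cell_id, true_cell_type and
#'   one logical truth column per marker) and `config`.
#' @examples
#' cohort <- generate_cells(make_preset("tonsil"))
#' head(cohort$cells)
#' @export
generate_cells <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  validate_generator_config(config)
  set.seed(config$seed)
  tissues <- lapply(seq_len(config$n_test_tissues), function(i) {
    list(tissue_id = sprintf("tissue_%02d", i), role = "test",
         compartments = config$compartments)
  })
  if (config$reference_included)
    tissues <- c(tissues, list(list(tissue_id = "reference_tonsil",
                                    role = "reference",
                                    compartments = config$reference_compartments)))

  cells_list <- list(); truth_list <- list(); idx <- 0L
  for (tis in tissues) {
    for (comp in tis$compartments) {
      n <- comp$n_cells
      types <- sample(names(comp$cell_type_proportions), n, replace = TRUE,
                      prob = comp$cell_type_proportions)
      # positions uniform in the spot disc, in micrometres
      r <- (config$spot_diameter_mm * 500) * sqrt(stats::runif(n))
      th <- 2 * pi * stats::runif(n)
      idmat <- matrix(NA_real_, nrow = n, ncol = length(config$panel$markers),
                      dimnames = list(NULL, config$panel$markers))
      posmat <- matrix(FALSE, nrow = n, ncol = length(config$panel$markers),
                       dimnames = list(NULL, config$panel$markers))
      for (ct in unique(types)) {
        ii <- which(types == ct)
        m <- length(ii)
        # joint checkpoint positivity through the copula
        pT <- effective_pos_fraction(config, comp, ct, "TIGIT")
        pP <- effective_pos_fraction(config, comp, ct, "PD-1")
        cp <- effective_copositivity(config, comp, ct)
        p11 <- unname(cp[["p_pd1_given_tigit"]]) * pT
        if (pT == 0 || pP == 0) {
          posT <- stats::runif(m) < pT
          posP <- stats::runif(m) < pP
        } else {
          rho <- solve_copula_rho(pT, pP, p11)
          z1 <- stats::rnorm(m)
          z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(m)
          posT <- z1 < stats::qnorm(pT)
          posP <- z2 < stats::qnorm(pP)
        }
        for (mk in config$panel$markers) {
          mx <- config$mixtures[[ct]][[mk]]
          pos <- switch(mk,
                        "TIGIT" = posT,
                        "PD-1"  = posP,
                        stats::runif(m) < effective_pos_fraction(config, comp, ct, mk))
          mu <- ifelse(pos, effective_pos_log_mean(config, comp, ct, mk),
                       mx$neg_log_mean)
          sd <- ifelse(pos, mx$pos_log_sd, mx$neg_log_sd)
          idmat[ii, mk] <- stats::rlnorm(m, meanlog = mu, sdlog = sd)
          posmat[ii, mk] <- pos
        }
      }
      ids <- sprintf("%s_%s_c%05d", tis$tissue_id, comp$name, seq_len(n))
      base <- data.frame(cell_id = ids, tissue_id = tis$tissue_id,
                         tissue_role = tis$role, compartment = comp$name,
                         x_um = r * cos(th), y_um = r * sin(th),
                         stringsAsFactors = FALSE, check.names = FALSE)
      cells_list[[idx + 1L]] <- cbind(base,
                                      as.data.frame(idmat, check.names = FALSE))
      tr <- data.frame(cell_id = ids, true_cell_type = types,
                       stringsAsFactors = FALSE, check.names = FALSE)
      tr <- cbind(tr, as.data.frame(posmat, check.names = FALSE))
      names(tr)[-(1:2)] <- paste0(config$panel$markers, "_truth_pos")
      truth_list[[idx + 1L]] <- tr
      idx <- idx + 1L
    }
  }
  cells <- do.call(rbind, cells_list)
  truth <- do.call(rbind, truth_list)
  rownames(cells) <- rownames(truth) <- NULL
  structure(list(cells = cells, truth = truth, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Synthetic MF-IHC cohort: %d cells, %d tissue(s), seed %d\n",
              nrow(x$cells), length(unique(x$cells$tissue_id)), x$config$seed))
  print(table(x$cells$tissue_id, x$cells$compartment))
  invisible(x)
}
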