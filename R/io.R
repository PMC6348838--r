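.cell_meta_cols <- c("cell_id", "tissue_id", "tissue_role", "compartment",
                     "x_um", "y_um")

#' Write / read a per-cell intensity table
#'
#' Cell tables are plain CSV with the header
#' `cell_id, tissue_id, tissue_role, compartment, x_um, y_um` followed by
#' one raw-intensity column per panel marker. `read_cells()` validates the
#' schema (all panel markers present, intensities non-negative, optionally
#' compartment labels drawn from a known set) and reports offending row
#' numbers. The round trip `read_cells(write_cells(x))` reproduces `x`
#' field for field.
#'
#' @param cells Cell data frame (e.g. `generate_cells(...)$cells`).
#' @param path File path.
#' @param panel [marker_panel()] used to validate intensity columns.
#' @param compartments Optional character vector of valid compartment
#'   labels; unknown labels become a parse error.
#' @return `write_cells()` returns `path` invisibly; `read_cells()` the
#'   validated data frame.
#' @export
write_cells <- function(cells, path, panel = marker_panel()) {
  missing <- setdiff(c(.cell_meta_cols, panel$markers), names(cells))
  if (length(missing))
    mfi_stop("mfi_schema_error", "cell table lacks column(s): %s",
             paste(missing, collapse = ", "))
  utils::write.csv(cells[, c(.cell_meta_cols, panel$markers)], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cells
#' @export
read_cells <- function(path, panel = marker_panel(), compartments = NULL) {
  if (!file.exists(path))
    mfi_stop("mfi_io_error", "file not found: %s", path)
  cells <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(c(.cell_meta_cols, panel$markers), names(cells))
  if (length(missing))
    mfi_stop("mfi_parse_error", "cell table %s lacks column(s): %s",
             path, paste(missing, collapse = ", "))
  for (mk in panel$markers) {
    v <- cells[[mk]]
    if (!is.numeric(v))
      mfi_stop("mfi_parse_error", "column '%s' is not numeric", mk)
    bad <- which(v < 0 | !is.finite(v))
    if (length(bad))
      mfi_stop("mfi_parse_error",
               "non-negative finite intensity required: column '%s', row %d has value %s",
               mk, bad[1], format(v[bad[1]]))
  }
  if (!is.null(compartments)) {
    bad <- which(!(cells$compartment %in% compartments))
    if (length(bad))
      mfi_stop("mfi_parse_error", "unknown compartment '%s' at row %d",
               cells$compartment[bad[1]], bad[1])
  }
  cells
}

#' Write / read the generator ground-truth sidecar table
#'
#' @param truth Truth data frame (`generate_cells(...)$truth`).
#' @param path File path.
#' @return `write_truth()` returns `path` invisibly; `read_truth()` the
#'   data frame with logical truth columns.
#' @export
write_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

# --- generator configuration <-> YAML --------------------------------------

config_to_list <- function(cfg) {
  list(
    panel = list(lineage_markers = cfg$panel$lineage_markers,
                 checkpoint_markers = cfg$panel$checkpoint_markers),
    compartments = lapply(cfg$compartments, comp_to_list),
    mixtures = lapply(cfg$mixtures, function(mx) lapply(mx, unclass)),
    copositivity = lapply(cfg$copositivity, as.list),
    spot_diameter_mm = cfg$spot_diameter_mm,
    seed = cfg$seed,
    reference_included = cfg$reference_included,
    reference_compartments = lapply(cfg$reference_compartments, comp_to_list),
    n_test_tissues = cfg$n_test_tissues,
    n_cells_range = cfg$n_cells_range
  )
}

comp_to_list <- function(comp) {
  list(name = comp$name, n_cells = comp$n_cells,
       cell_type_proportions = as.list(comp$cell_type_proportions),
       checkpoint_gradient = as.list(comp$checkpoint_gradient),
       pos_fraction_overrides = lapply(comp$pos_fraction_overrides, as.list),
       copositivity_overrides = lapply(comp$copositivity_overrides, as.list))
}

comp_from_list <- function(x) {
  compartment_spec(x$name, x$n_cells,
                   unlist(x$cell_type_proportions),
                   checkpoint_gradient = unlist(x$checkpoint_gradient),
                   pos_fraction_overrides =
                     lapply(x$pos_fraction_overrides, unlist),
                   copositivity_overrides =
                     lapply(x$copositivity_overrides, unlist))
}

#' Serialize a generator configuration to YAML
#'
#' The YAML mirrors the [generator_config()] field names exactly, so a
#' resolved configuration written next to a simulated cohort fully
#' documents its provenance and can be read back and re-run.
#'
#' @param config A [generator_config()].
#' @param path File path.
#' @return `write_generator_config()` returns `path` invisibly;
#'   `read_generator_config()` a validated [generator_config()].
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  x <- yaml::read_yaml(path)
  mixtures <- lapply(x$mixtures, function(mx)
    lapply(mx, function(m) do.call(intensity_mixture, m)))
  generator_config(
    panel = marker_panel(unlist(x$panel$lineage_markers),
                         unlist(x$panel$checkpoint_markers)),
    compartments = lapply(x$compartments, comp_from_list),
    mixtures = mixtures,
    copositivity = lapply(x$copositivity, unlist),
    spot_diameter_mm = x$spot_diameter_mm,
    seed = x$seed,
    reference_included = x$reference_included,
    reference_compartments = lapply(x$reference_compartments, comp_from_list),
    n_test_tissues = x$n_test_tissues,
    n_cells_range = unlist(x$n_cells_range)
  )
}

#' Serialize a calibrated threshold set to YAML
#'
#' @param thresholds A `threshold_set` (see [calibrate_thresholds()]).
#' @param path File path.
#' @return `write_thresholds()` returns `path` invisibly;
#'   `read_thresholds()` a `threshold_set`.
#' @export
write_thresholds <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "threshold_set"))
  yaml::write_yaml(list(cutoffs = as.list(thresholds$cutoffs),
                        n_negative_cells = as.list(thresholds$n_negative_cells),
                        negative_selector = as.list(thresholds$negative_selector),
                        window = thresholds$window),
                   path)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  x <- yaml::read_yaml(path)
  new_threshold_set(unlist(x$cutoffs), unlist(x$n_negative_cells),
                    unlist(x$negative_selector), unlist(x$window))
}

#' Write a phenotype table to CSV
#'
#' @param pheno Phenotype data frame from [call_positivity()] /
#'   [assign_cell_type()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
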