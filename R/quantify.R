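marker_values <- function(x, marker) {
  if (is.data.frame(x)) {
    if (!marker %in% names(x))
      mfi_stop("mfi_schema_error", "marker '%s' not present in the cell table", marker)
    x[[marker]]
  } else if (is.numeric(x)) {
    x
  } else {
    mfi_stop("mfi_argument_error", "expected a cell table or a numeric vector")
  }
}

#' Reference-normalized relative expression (RE)
#'
#' The mean raw intensity of the reference cells is set to 100% and the
#' test cells' mean raw intensity is expressed as a percentage of it:
#' `RE = 100 * mean(test) / mean(reference)`. Using the reference cells as
#' their own test set gives exactly 100.
#'
#' @param test_cells,reference_cells Cell tables containing `marker`, or
#'   numeric intensity vectors.
#' @param marker Marker name (ignored for numeric input).
#' @return RE in percent (scale 0-100-plus).
#' @examples
#' relative_expression(c(40, 60), c(150, 250))  # 25
#' @export
relative_expression <- function(test_cells, reference_cells, marker = NULL) {
  tv <- if (is.data.frame(test_cells)) marker_values(test_cells, marker) else test_cells
  rv <- if (is.data.frame(reference_cells)) marker_values(reference_cells, marker) else reference_cells
  if (length(tv) == 0L || length(rv) == 0L)
    mfi_stop("mfi_insufficient_cells_error",
             "relative expression needs non-empty test and reference cell sets")
  rm_ <- mean(rv)
  if (rm_ == 0)
    mfi_stop("mfi_reference_error",
             "reference mean intensity is zero; relative expression undefined")
  # parenthesized so a test set equal to the reference gives exactly 100
  100 * (mean(tv) / rm_)
}

#' TIGIT : PD-1 expression ratio
#'
#' Ratio of the two checkpoint markers' relative expressions in the same
#' cell population. Undefined (error) when the PD-1 RE is not positive.
#'
#' @param re_tigit,re_pd1 Relative expressions in percent.
#' @return The dimensionless ratio (vectorized).
#' @examples
#' tigit_pd1_ratio(80, 40)  # 2
#' @export
tigit_pd1_ratio <- function(re_tigit, re_pd1) {
  if (any(!is.finite(re_pd1)) || any(re_pd1 <= 0))
    mfi_stop("mfi_ratio_error", "TIGIT:PD-1 ratio undefined for RE[PD-1] <= 0")
  re_tigit / re_pd1
}

#' TIGIT / PD-1 coexpression fractions
#'
#' Conditional fractions P(PD-1+ | TIGIT+) and P(TIGIT+ | PD-1+) over a
#' scoped set of gated cells. A conditional with an empty denominator is
#' reported as `NA` (undefined), never as 0.
#'
#' @param pheno Phenotype table with TIGIT and PD-1 calls.
#' @param scope Optional row selection: logical vector or cell ids.
#' @return A list of class `coexpression_result` with the two fractions
#'   and the underlying counts.
#' @export
coexpression_fractions <- function(pheno, scope = NULL) {
  if (!all(c("TIGIT", "PD-1") %in% names(pheno)))
    mfi_stop("mfi_schema_error", "phenotype table lacks checkpoint calls")
  if (!is.null(scope)) {
    pheno <- if (is.logical(scope)) pheno[scope, ] else
      pheno[pheno$cell_id %in% scope, ]
  }
  t_pos <- pheno$TIGIT; p_pos <- pheno$`PD-1`
  n_t <- sum(t_pos); n_p <- sum(p_pos); n_tp <- sum(t_pos & p_pos)
  structure(list(
    frac_tigit_pos_that_are_pd1_pos = if (n_t > 0) n_tp / n_t else NA_real_,
    frac_pd1_pos_that_are_tigit_pos = if (n_p > 0) n_tp / n_p else NA_real_,
    n_tigit_pos = n_t, n_pd1_pos = n_p, n_double_pos = n_tp,
    n_cells = nrow(pheno)),
    class = "coexpression_result")
}

#' @export
print.coexpression_result <- function(x, ...) {
  cat(sprintf("TIGIT/PD-1 coexpression over %d cells\n", x$n_cells))
  cat(sprintf("  P(PD-1+ | TIGIT+) = %s  (%d / %d)\n",
              format(round(x$frac_tigit_pos_that_are_pd1_pos, 3)),
              x$n_double_pos, x$n_tigit_pos))
  cat(sprintf("  P(TIGIT+ | PD-1+) = %s  (%d / %d)\n",
              format(round(x$frac_pd1_pos_that_are_tigit_pos, 3)),
              x$n_double_pos, x$n_pd1_pos))
  invisible(x)
}

#' Marker positivity fraction within a gated cell type
#'
#' Fraction of cells carrying `cell_type` (per [assign_cell_type()]) that
#' are called positive for `marker`. `require` optionally restricts the
#' denominator to cells also positive for the listed markers — e.g.
#' `require = "CD3"` reports positivity among CD4+ *T* cells.
#'
#' @param pheno Phenotype table with `cell_type` filled.
#' @param cell_type Cell-type label.
#' @param marker Marker whose positivity is reported.
#' @param require Optional character vector of markers that must also be
#'   positive for a cell to enter the denominator.
#' @return Fraction in `[0, 1]`, or `NA` if no cell qualifies.
#' @export
positivity_fraction <- function(pheno, cell_type, marker, require = NULL) {
  if (!"cell_type" %in% names(pheno))
    mfi_stop("mfi_schema_error", "run assign_cell_type() first")
  keep <- pheno$cell_type == cell_type
  for (mk in require) keep <- keep & pheno[[mk]]
  n <- sum(keep)
  if (n == 0L) return(NA_real_)
  sum(pheno[[marker]][keep]) / n
}

#' Circular tissue-spot geometry
#'
#' @param diameter_mm Spot diameter in millimetres (e.g. 0.6 for a
#'   multitumour TMA core, 4 for a microenvironment TMA punch).
#' @return Object of class `spot_geometry` with `diameter_mm` and the
#'   derived `area_mm2`.
#' @export
spot_geometry <- function(diameter_mm) {
  if (!is.numeric(diameter_mm) || length(diameter_mm) != 1L ||
      !is.finite(diameter_mm) || diameter_mm <= 0)
    mfi_stop("mfi_geometry_error", "spot diameter must be a positive number")
  structure(list(diameter_mm = diameter_mm,
                 area_mm2 = pi * (diameter_mm / 2)^2),
            class = "spot_geometry")
}

#' Cell density per square millimetre
#'
#' Converts a cell count on a circular tissue spot into cells per mm^2.
#'
#' @param count Non-negative cell count (vectorized).
#' @param geometry A [spot_geometry()].
#' @return Density in cells/mm^2.
#' @examples
#' cell_density(80, spot_geometry(0.6))  # ~282.9 cells/mm^2
#' @export
cell_density <- function(count, geometry) {
  stopifnot(inherits(geometry, "spot_geometry"))
  if (any(count < 0))
    mfi_stop("mfi_argument_error", "cell count must be non-negative")
  count / geometry$area_mm2
}

#' Cell density per 0.1 square millimetre
#'
#' @param count Non-negative cell count (vectorized).
#' @param region_area_mm2 Area of the counted region in mm^2.
#' @return Cells per 0.1 mm^2.
#' @export
density_per_0p1mm2 <- function(count, region_area_mm2) {
  if (!is.numeric(region_area_mm2) || any(region_area_mm2 <= 0))
    mfi_stop("mfi_geometry_error", "region area must be positive")
  if (any(count < 0))
    mfi_stop("mfi_argument_error", "cell count must be non-negative")
  count * 0.1 / region_area_mm2
}

#' Per-compartment expression summaries
#'
#' For every (tissue, compartment, cell type) combination computes the
#' number of gated cells, the mean raw checkpoint intensities, the
#' reference-normalized relative expression of each checkpoint marker and
#' the TIGIT:PD-1 ratio of the two REs. The reference population is
#' type-matched by default: test cells of type X are normalized against
#' reference-tissue cells of the same type X in the reference compartment
#' (a pooled reference over all listed cell types is available but off by
#' default). Rows with fewer cells than `min_n` are flagged `low_n`.
#'
#' @param cells Cell table (raw intensities).
#' @param pheno Phenotype table with `cell_type` assigned.
#' @param reference List naming the reference population: either
#'   `tissue_id` or `tissue_role` (default `"reference"`), plus
#'   `compartment` (default `"Gcp"`, the tonsil germinal-centre periphery;
#'   set `"Gcc"` for the germinal centre proper).
#' @param cell_types Cell types summarized (default the three T-cell
#'   subtypes shown in the study figures).
#' @param markers Checkpoint markers to summarize.
#' @param min_n Minimum gated-cell count before a row is flagged low-n.
#' @param pooled_reference If `TRUE`, one reference mean pooled over all
#'   `cell_types` is used for every row instead of type-matched means.
#' @return Data frame of class `compartment_summary`.
#' @export
summarize_compartments <- function(cells, pheno,
                                   reference = list(tissue_role = "reference",
                                                    compartment = "Gcp"),
                                   cell_types = c("CD4_T", "CD8_T", "FOXP3_Treg"),
                                   markers = c("TIGIT", "PD-1"),
                                   min_n = 20, pooled_reference = FALSE) {
  if (!"cell_type" %in% names(pheno))
    mfi_stop("mfi_schema_error", "run assign_cell_type() first")
  ct_of <- pheno$cell_type[match(cells$cell_id, pheno$cell_id)]
  ref_rows <- if (!is.null(reference$tissue_id))
    cells$tissue_id == reference$tissue_id else
    cells$tissue_role == (reference$tissue_role %||% "reference")
  ref_rows <- ref_rows & cells$compartment == reference$compartment
  if (!any(ref_rows))
    mfi_stop("mfi_reference_error",
             "reference population (%s, compartment '%s') not present in the data",
             reference$tissue_id %||% reference$tissue_role %||% "reference",
             reference$compartment)

  ref_mean <- function(ct, mk) {
    keep <- ref_rows & (if (pooled_reference) ct_of %in% cell_types else ct_of == ct)
    v <- cells[[mk]][keep]
    if (length(v) == 0L) return(NA_real_)
    mean(v)
  }

  combos <- unique(data.frame(tissue_id = cells$tissue_id,
                              compartment = cells$compartment,
                              stringsAsFactors = FALSE))
  out <- list()
  for (i in seq_len(nrow(combos))) {
    for (ct in cell_types) {
      keep <- cells$tissue_id == combos$tissue_id[i] &
        cells$compartment == combos$compartment[i] & ct_of == ct
      n <- sum(keep)
      row <- list(tissue_id = combos$tissue_id[i],
                  compartment = combos$compartment[i],
                  cell_type = ct, n_cells = n)
      res <- numeric(0)
      for (mk in markers) {
        m <- if (n > 0) mean(cells[[mk]][keep]) else NA_real_
        rmean <- ref_mean(ct, mk)
        row[[paste0("mean_", mk)]] <- m
        res[mk] <- if (is.na(m) || is.na(rmean) || rmean == 0) NA_real_ else
          100 * (m / rmean)  # parenthesized: reference vs itself is exactly 100
        row[[paste0("RE_", mk)]] <- res[mk]
      }
      row$ratio_tigit_pd1 <-
        if (all(c("TIGIT", "PD-1") %in% markers) && !anyNA(res) && res[["PD-1"]] > 0)
          res[["TIGIT"]] / res[["PD-1"]] else NA_real_
      row$low_n <- n < min_n
      out[[length(out) + 1L]] <- as.data.frame(row, check.names = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("compartment_summary", "data.frame")
  out
}
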