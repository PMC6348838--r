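new_threshold_set <- function(cutoffs, n_negative_cells, negative_selector,
                              window = c(50, 200)) {
  if (any(cutoffs < 0) || any(!is.finite(cutoffs)))
    mfi_stop("mfi_calibration_error", "cutoffs must be finite and >= 0")
  structure(list(cutoffs = cutoffs, n_negative_cells = n_negative_cells,
                 negative_selector = negative_selector,
                 window = as.numeric(window)),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("Per-marker positivity cutoffs (raw intensity units)\n")
  df <- data.frame(marker = names(x$cutoffs),
                   cutoff = round(unname(x$cutoffs), 4),
                   n_negative = unname(x$n_negative_cells[names(x$cutoffs)]),
                   selector = unname(x$negative_selector[names(x$cutoffs)]))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Default negative-control selection rules
#'
#' Maps each marker to the anchor lineage used to enrich cells expected to
#' lack it. B cells (CD20) carry none of the other panel markers — in
#' particular they show no unequivocal TIGIT staining — so every non-CD20
#' marker is calibrated on CD20-enriched cells; CD20 itself is calibrated
#' on CD3-enriched T cells.
#'
#' @param panel A [marker_panel()].
#' @return Named character vector: marker -> anchor marker.
#' @export
default_negative_rules <- function(panel = marker_panel()) {
  rules <- stats::setNames(rep("CD20", length(panel$markers)), panel$markers)
  if ("CD20" %in% names(rules)) rules[["CD20"]] <- "CD3"
  rules
}

#' Select negative-control cells for threshold calibration
#'
#' Returns a reproducible sample of cell ids expected to lack `marker`.
#' The selection rule is either an anchor marker name — cells are ranked by
#' the anchor's *raw* intensity and the top-ranked cells form the eligible
#' pool (rank enrichment needs no pre-existing threshold, which breaks the
#' circularity of gating-based selection) — or an explicit eligibility
#' specification (a vector of cell ids, or a logical mask over rows).
#'
#' @param cells Cell table.
#' @param marker Marker being calibrated.
#' @param rule Anchor marker name (default from [default_negative_rules()]),
#'   a character vector of eligible cell ids, or a logical vector.
#' @param max_n Maximum number of controls to draw (upper end of the
#'   calibration window).
#' @param min_n Minimum number of eligible cells required.
#' @param seed Integer seed for the (uniform, without replacement) draw.
#' @return Character vector of selected cell ids.
#' @export
select_negative_controls <- function(cells, marker,
                                     rule = default_negative_rules()[[marker]],
                                     max_n = 200, min_n = 50, seed = 1) {
  if (!marker %in% names(cells))
    mfi_stop("mfi_schema_error", "marker '%s' not present in the cell table", marker)
  if (is.function(rule)) rule <- rule(cells)
  if (is.logical(rule)) {
    stopifnot(length(rule) == nrow(cells))
    eligible <- cells$cell_id[rule]
  } else if (is.character(rule) && length(rule) == 1L && rule %in% names(cells)) {
    # anchor-marker rank enrichment: pool of the 2*max_n brightest anchor cells
    pool_n <- min(nrow(cells), 2L * max_n)
    ord <- order(cells[[rule]], decreasing = TRUE)
    eligible <- cells$cell_id[ord[seq_len(pool_n)]]
  } else if (is.character(rule)) {
    eligible <- intersect(rule, cells$cell_id)
  } else {
    mfi_stop("mfi_argument_error", "unsupported negative-control rule")
  }
  if (length(eligible) < min_n)
    mfi_stop("mfi_calibration_error",
             "only %d eligible negative-control cells for marker '%s' (need >= %d); use a larger input region",
             length(eligible), marker, min_n)
  set.seed(seed)
  sort(sample(eligible, min(max_n, length(eligible))))
}

#' Calibrate a positivity threshold from negative-control cells
#'
#' The cutoff for a marker is the highest raw intensity observed among the
#' negative-control cells — i.e. the brightest "false positive"
#' measurement defines the positivity threshold. The number of controls
#' must lie inside the calibration window (default 50-200 cells).
#'
#' @param cells Cell table.
#' @param marker Marker name.
#' @param negative_cell_ids Character vector of control cell ids.
#' @param window Length-2 numeric, allowed control-count window.
#' @return The cutoff (a single non-negative number).
#' @examples
#' cells <- data.frame(cell_id = as.character(1:60), TIGIT = 1:60)
#' calibrate_threshold(cells, "TIGIT", cells$cell_id)  # 60
#' @export
calibrate_threshold <- function(cells, marker, negative_cell_ids,
                                window = c(50, 200)) {
  if (!marker %in% names(cells))
    mfi_stop("mfi_schema_error", "marker '%s' not present in the cell table", marker)
  n <- length(negative_cell_ids)
  if (n < window[1] || n > window[2])
    mfi_stop("mfi_calibration_error",
             "negative-control set for '%s' has %d cells, outside the calibration window [%d, %d]",
             marker, n, window[1], window[2])
  idx <- match(negative_cell_ids, cells$cell_id)
  if (anyNA(idx))
    mfi_stop("mfi_calibration_error",
             "negative-control id(s) not found in the cell table: %s",
             paste(utils::head(negative_cell_ids[is.na(idx)], 3), collapse = ", "))
  max(cells[[marker]][idx])
}

#' Calibrate the full panel of positivity thresholds
#'
#' Applies [select_negative_controls()] and [calibrate_threshold()] to
#' every marker in the panel and returns a `threshold_set` recording each
#' cutoff together with its calibration provenance (control count and
#' selector description).
#'
#' @param cells Cell table (typically one tissue slide).
#' @param panel A [marker_panel()].
#' @param rules Named rule map as in [select_negative_controls()].
#' @param max_n Maximum controls per marker.
#' @param window Allowed control-count window.
#' @param seed Integer seed; each marker uses `seed + its panel index`.
#' @return A `threshold_set`.
#' @export
calibrate_thresholds <- function(cells, panel = marker_panel(),
                                 rules = default_negative_rules(panel),
                                 max_n = 200, window = c(50, 200), seed = 1) {
  cutoffs <- numeric(0); nneg <- integer(0); sel <- character(0)
  for (i in seq_along(panel$markers)) {
    mk <- panel$markers[i]
    rule <- rules[[mk]]
    ids <- select_negative_controls(cells, mk, rule, max_n = max_n,
                                    min_n = window[1], seed = seed + i)
    cutoffs[mk] <- calibrate_threshold(cells, mk, ids, window = window)
    nneg[mk] <- length(ids)
    sel[mk] <- if (is.character(rule) && length(rule) == 1L && rule %in% names(cells))
      sprintf("top cells by %s raw intensity", rule) else "explicit cell set"
  }
  new_threshold_set(cutoffs, nneg, sel, window)
}
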