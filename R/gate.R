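#' Call per-cell marker positivity against calibrated thresholds
#'
#' A cell is positive for a marker iff its raw intensity strictly exceeds
#' the marker's cutoff; an intensity exactly equal to the cutoff is
#' negative. Raising a cell's intensity can therefore never turn a
#' positive call negative.
#'
#' @param cells Cell table.
#' @param thresholds A `threshold_set` covering every panel marker.
#' @param panel A [marker_panel()].
#' @return A phenotype data frame: the cell metadata columns plus one
#'   logical column per marker.
#' @export
call_positivity <- function(cells, thresholds, panel = marker_panel()) {
  stopifnot(inherits(thresholds, "threshold_set"))
  missing <- setdiff(panel$markers, names(thresholds$cutoffs))
  if (length(missing))
    mfi_stop("mfi_schema_error", "thresholds lack cutoff(s) for: %s",
             paste(missing, collapse = ", "))
  missing <- setdiff(c(.cell_meta_cols, panel$markers), names(cells))
  if (length(missing))
    mfi_stop("mfi_schema_error", "cell table lacks column(s): %s",
             paste(missing, collapse = ", "))
  pheno <- cells[, .cell_meta_cols]
  for (mk in panel$markers)
    pheno[[mk]] <- cells[[mk]] > unname(thresholds$cutoffs[[mk]])
  pheno
}

#' Assign cell-type labels from lineage positivity
#'
#' Deterministic first-match precedence over the lineage calls:
#' FOXP3+ -> `FOXP3_Treg`; else CD8+ -> `CD8_T`; else CD4+ -> `CD4_T`;
#' else CD3+ -> `CD3_T`; else CD20+ -> `CD20_B`; else CD56+ -> `CD56_NK`;
#' else CD11c+ -> `CD11c_DC`; else CD68+ -> `CD68_Mac`; else `other`.
#' Also derives the joint checkpoint state of the two checkpoint calls.
#'
#' @param pheno Phenotype table from [call_positivity()].
#' @return `pheno` with `cell_type` and `checkpoint_state` columns filled.
#' @export
assign_cell_type <- function(pheno) {
  missing <- setdiff(.cell_type_precedence$marker, names(pheno))
  if (length(missing))
    mfi_stop("mfi_schema_error", "phenotype table lacks lineage call(s): %s",
             paste(missing, collapse = ", "))
  ct <- rep("other", nrow(pheno))
  # apply in reverse precedence so the highest-precedence marker wins
  for (i in rev(seq_len(nrow(.cell_type_precedence)))) {
    mk <- .cell_type_precedence$marker[i]
    ct[pheno[[mk]]] <- .cell_type_precedence$cell_type[i]
  }
  pheno$cell_type <- ct
  if (all(c("TIGIT", "PD-1") %in% names(pheno)))
    pheno$checkpoint_state <- paste0(ifelse(pheno$TIGIT, "TIGIT+", "TIGIT-"),
                                     ifelse(pheno$`PD-1`, "PD1+", "PD1-"))
  pheno
}
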