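#' Define a multiplex immunofluorescence marker panel
#'
#' A panel is the set of lineage markers used for phenotyping plus the
#' checkpoint markers whose expression is quantified. The default panel is
#' the ten-colour panel used throughout the package: eight lineage markers
#' (CD3, CD4, CD8, FOXP3, CD20, CD56, CD11c, CD68) and the two inhibitory
#' checkpoint receptors TIGIT and PD-1.
#'
#' @param lineage_markers Character vector of lineage marker names.
#' @param checkpoint_markers Character vector of checkpoint marker names.
#' @return An object of class `marker_panel`: a list with elements
#'   `lineage_markers`, `checkpoint_markers` and `markers` (their union, in
#'   column order).
#' @examples
#' panel <- marker_panel()
#' panel$markers
#' @export
marker_panel <- function(lineage_markers = c("CD3", "CD4", "CD8", "FOXP3",
                                             "CD20", "CD56", "CD11c", "CD68"),
                         checkpoint_markers = c("TIGIT", "PD-1")) {
  all <- c(lineage_markers, checkpoint_markers)
  if (anyDuplicated(all))
    mfi_stop("mfi_config_error", "marker names must be unique across the panel; duplicated: %s",
             paste(unique(all[duplicated(all)]), collapse = ", "))
  if (length(checkpoint_markers) < 1L)
    mfi_stop("mfi_config_error", "panel needs at least one checkpoint marker")
  structure(list(lineage_markers = lineage_markers,
                 checkpoint_markers = checkpoint_markers,
                 markers = all),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("Marker panel\n")
  cat("  lineage:   ", paste(x$lineage_markers, collapse = ", "), "\n")
  cat("  checkpoint:", paste(x$checkpoint_markers, collapse = ", "), "\n")
  invisible(x)
}

# Cell-type labels the gating module can assign, in precedence order
# (first positive lineage in this order wins; see assign_cell_type()).
.cell_type_precedence <- data.frame(
  marker    = c("FOXP3", "CD8", "CD4", "CD3", "CD20", "CD56", "CD11c", "CD68"),
  cell_type = c("FOXP3_Treg", "CD8_T", "CD4_T", "CD3_T", "CD20_B", "CD56_NK",
                "CD11c_DC", "CD68_Mac"),
  stringsAsFactors = FALSE
)

#' Cell-type labels used by the gating module
#'
#' @return Character vector of assignable labels, precedence order first,
#'   ending with the fallback `"other"`.
#' @export
cell_type_labels <- function() c(.cell_type_precedence$cell_type, "other")
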