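#' Quantify checkpoint expression from a per-cell intensity table
#'
#' Runs the full measurement chain on a gated multiplex immunofluorescence
#' cell table: per-marker threshold calibration from negative-control
#' cells (per tissue slide by default), positivity calling, cell-type
#' assignment, per-compartment reference-normalized summaries
#' (RE[TIGIT], RE[PD-1], TIGIT:PD-1 ratio), checkpoint coexpression
#' fractions and compartment comparisons by one-way ANOVA.
#'
#' @param cells Cell table (see [read_cells()] / [generate_cells()]).
#' @param panel A [marker_panel()].
#' @param reference Reference population for RE normalization, as in
#'   [summarize_compartments()]. Default: the reference tissue's tonsil
#'   germinal-centre periphery (`Gcp`).
#' @param rules Negative-control rules ([default_negative_rules()]).
#' @param max_n,window Negative-control count cap and calibration window.
#' @param min_n Low-n flagging threshold for summary rows.
#' @param cell_types Cell types summarized and compared.
#' @param calibrate_by `"tissue"` (a threshold set per tissue slide,
#'   default) or `"global"` (one threshold set for the whole table).
#' @param posthoc If `TRUE`, adds pairwise Welch/Holm compartment tests
#'   (per cell type and marker, cell-level units).
#' @param seed Integer seed for the negative-control draws.
#' @return Object of class `mfi_quant` with elements `thresholds` (named
#'   list per tissue), `phenotypes`, `summaries`, `comparisons`,
#'   `coexpression`, `posthoc`, `params` and `config_hash`.
#' @examples
#' cohort <- generate_cells(make_preset("tonsil"))
#' fit <- mfi_quantify(cohort$cells)
#' summary(fit)
#' @export
mfi_quantify <- function(cells, panel = marker_panel(),
                         reference = list(tissue_role = "reference",
                                          compartment = "Gcp"),
                         rules = default_negative_rules(panel),
                         max_n = 200, window = c(50, 200), min_n = 20,
                         cell_types = c("CD4_T", "CD8_T", "FOXP3_Treg"),
                         calibrate_by = c("tissue", "global"),
                         posthoc = FALSE, seed = 1) {
  calibrate_by <- match.arg(calibrate_by)
  tissues <- unique(cells$tissue_id)
  thresholds <- list(); pheno_parts <- list()
  if (calibrate_by == "global") {
    ts <- calibrate_thresholds(cells, panel, rules, max_n = max_n,
                               window = window, seed = seed)
    thresholds <- stats::setNames(rep(list(ts), length(tissues)), tissues)
    pheno <- assign_cell_type(call_positivity(cells, ts, panel))
  } else {
    for (i in seq_along(tissues)) {
      sub <- cells[cells$tissue_id == tissues[i], , drop = FALSE]
      ts <- calibrate_thresholds(sub, panel, rules, max_n = max_n,
                                 window = window, seed = seed + 1000L * i)
      thresholds[[tissues[i]]] <- ts
      pheno_parts[[i]] <- call_positivity(sub, ts, panel)
    }
    pheno <- assign_cell_type(do.call(rbind, pheno_parts))
  }

  summaries <- summarize_compartments(cells, pheno, reference = reference,
                                      cell_types = cell_types, min_n = min_n)
  test_tissues <- unique(cells$tissue_id[cells$tissue_role == "test"])
  n_test_comp <- length(unique(cells$compartment[cells$tissue_role == "test"]))
  comparisons <- NULL
  if (n_test_comp >= 2L) {
    unit <- if (length(test_tissues) > 1L) "tissue" else "cell"
    comparisons <- compare_groups(
      cells = cells, pheno = pheno,
      summaries = summaries[summaries$tissue_id %in% test_tissues, ],
      cell_types = cell_types, unit = unit)
  }
  post <- NULL
  if (isTRUE(posthoc) && n_test_comp >= 2L) {
    ct_of <- pheno$cell_type[match(cells$cell_id, pheno$cell_id)]
    post <- list()
    for (ct in cell_types) for (mk in panel$checkpoint_markers) {
      keep <- ct_of == ct & cells$tissue_role == "test"
      post[[paste(ct, mk, sep = ".")]] <-
        pairwise_welch(cells[[mk]][keep], cells$compartment[keep])
    }
  }
  coex <- coexpression_fractions(pheno, scope = pheno$tissue_role == "test")
  params <- list(reference = reference, rules = as.list(rules), max_n = max_n,
                 window = window, min_n = min_n, cell_types = cell_types,
                 calibrate_by = calibrate_by, seed = seed)
  structure(list(thresholds = thresholds, phenotypes = pheno,
                 summaries = summaries, comparisons = comparisons,
                 coexpression = coex, posthoc = post, params = params,
                 config_hash = fnv1a_hash(paste(deparse(params), collapse = ""))),
            class = "mfi_quant")
}

#' @export
print.mfi_quant <- function(x, ...) {
  cat("Multiplex IF checkpoint quantification\n")
  cat(sprintf("  %d cells, %d tissue(s); config %s, seed %d\n",
              nrow(x$phenotypes), length(x$thresholds), x$config_hash,
              x$params$seed))
  cat(sprintf("  reference: %s / compartment %s\n",
              x$params$reference$tissue_id %||%
                x$params$reference$tissue_role %||% "reference",
              x$params$reference$compartment))
  print(x$coexpression)
  cat(sprintf("  %d summary rows; use summary() for the compartment table\n",
              nrow(x$summaries)))
  invisible(x)
}

#' @export
summary.mfi_quant <- function(object, digits = 2, ...) {
  s <- object$summaries
  num <- vapply(s, is.numeric, logical(1))
  s[num] <- lapply(s[num], round, digits)
  cat("Per-compartment relative expression (% of reference) and ratios\n")
  print(as.data.frame(s), row.names = FALSE)
  if (!is.null(object$comparisons)) {
    cat("\nCompartment comparisons (one-way ANOVA)\n")
    cmp <- object$comparisons
    cmp$F_stat <- signif(cmp$F_stat, 4)
    cmp$p_value <- signif(cmp$p_value, 3)
    print(cmp, row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.mfi_quant <- function(x, cell_type = "CD4_T", ...) {
  draw_panel(x$summaries, cell_type)
}
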