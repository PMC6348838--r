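#' Classical one-way fixed-effects ANOVA
#'
#' F statistic and upper-tail p-value from the F distribution with
#' (k-1, N-k) degrees of freedom, comparing group means of a numeric
#' response. When the between-group sum of squares is exactly zero (all
#' group means equal) the statistic is 0 with p = 1, including the fully
#' degenerate all-constant case.
#'
#' @param values Numeric response.
#' @param groups Grouping labels (coerced to factor), same length.
#' @return List with `F_stat`, `p_value`, `df` (numerator, denominator),
#'   `n_per_group` (named counts) and `stars` (see
#'   [significance_stars()]).
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  n <- table(groups)
  if (length(n) < 2L)
    mfi_stop("mfi_dof_error", "ANOVA needs at least two groups")
  if (any(n < 2L))
    mfi_stop("mfi_dof_error",
             "every group needs >= 2 observations (group '%s' has %d)",
             names(n)[which.min(n)], min(n))
  k <- length(n); N <- length(values)
  gm <- tapply(values, groups, mean)
  ssb <- sum(n * (gm - mean(values))^2)
  if (ssb == 0) {
    f <- 0; p <- 1
  } else {
    ow <- stats::oneway.test(values ~ groups, var.equal = TRUE)
    f <- unname(ow$statistic); p <- unname(ow$p.value)
  }
  list(F_stat = f, p_value = p, df = c(k - 1, N - k),
       n_per_group = as.vector(n), stars = significance_stars(p))
}

#' Significance tiers
#'
#' Maps a p-value onto the star annotation used in the report panels:
#' `p <= 0.0001` is `***`, `p <= 0.001` is `**`, `p <= 0.05` is `*`,
#' anything larger is `n.s.` (boundaries inclusive).
#'
#' @param p P-value(s) in `[0, 1]`.
#' @return Character vector of tiers.
#' @export
significance_stars <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    mfi_stop("mfi_argument_error", "p must be in [0, 1]")
  ifelse(p <= 0.0001, "***",
         ifelse(p <= 0.001, "**",
                ifelse(p <= 0.05, "*", "n.s.")))
}

#' Compare checkpoint expression across compartments or groups
#'
#' One ANOVA per (cell type, marker). With `unit = "cell"` the response is
#' the per-cell raw intensity of gated cells of the type, grouped by
#' compartment within the test tissue(s) — appropriate when a single
#' tissue is analysed. With `unit = "tissue"` the response is the
#' per-tissue relative expression from `summaries`, grouped by
#' compartment — the patient-level comparison for multi-patient panels.
#'
#' @param cells Cell table (needed for `unit = "cell"`).
#' @param pheno Phenotype table with `cell_type` (needed for
#'   `unit = "cell"`).
#' @param summaries A [summarize_compartments()] result (needed for
#'   `unit = "tissue"`).
#' @param cell_types,markers What to compare.
#' @param unit `"cell"` or `"tissue"` (see above).
#' @return Data frame: one row per comparison with `F_stat`, `p_value`,
#'   degrees of freedom, group sizes and `stars`.
#' @export
compare_groups <- function(cells = NULL, pheno = NULL, summaries = NULL,
                           cell_types = c("CD4_T", "CD8_T", "FOXP3_Treg"),
                           markers = c("TIGIT", "PD-1"),
                           unit = c("cell", "tissue")) {
  unit <- match.arg(unit)
  out <- list()
  for (ct in cell_types) {
    for (mk in markers) {
      if (unit == "cell") {
        stopifnot(!is.null(cells), !is.null(pheno))
        ct_of <- pheno$cell_type[match(cells$cell_id, pheno$cell_id)]
        keep <- ct_of == ct & cells$tissue_role == "test"
        values <- cells[[mk]][keep]
        groups <- cells$compartment[keep]
      } else {
        stopifnot(!is.null(summaries))
        rows <- summaries$cell_type == ct &
          summaries$tissue_id %in% unique(summaries$tissue_id)
        values <- summaries[[paste0("RE_", mk)]][rows]
        groups <- summaries$compartment[rows]
        keep_f <- is.finite(values)
        values <- values[keep_f]; groups <- groups[keep_f]
      }
      a <- one_way_anova(values, groups)
      out[[length(out) + 1L]] <- data.frame(
        cell_type = ct, marker = mk, unit = unit,
        F_stat = a$F_stat, p_value = a$p_value,
        df1 = a$df[1], df2 = a$df[2],
        n_per_group = paste(a$n_per_group, collapse = "/"),
        stars = a$stars, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Pairwise Welch t-tests with Holm adjustment
#'
#' Post-hoc pairwise compartment comparisons. This is an explicitly
#' labelled extension beyond the omnibus ANOVA and is off by default in
#' the pipeline.
#'
#' @param values Numeric response.
#' @param groups Grouping labels.
#' @param adjust Multiplicity adjustment method (see [stats::p.adjust()]).
#' @return Data frame with one row per group pair.
#' @export
pairwise_welch <- function(values, groups, adjust = "holm") {
  groups <- factor(groups)
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  res <- apply(pairs, 2, function(pr) {
    tt <- stats::t.test(values[groups == pr[1]], values[groups == pr[2]],
                        var.equal = FALSE)
    c(t = unname(tt$statistic), p = unname(tt$p.value))
  })
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    t = res["t", ], p_value = res["p", ],
                    stringsAsFactors = FALSE)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = adjust)
  out$stars <- significance_stars(out$p_adjusted)
  out
}
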