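## ---- Questionnaire scoring, Pearson correlations, generic group compare --

#' FSMC total score and severity label
#'
#' Total = motor + cognitive subscale; the cohort-level severity label is
#' "severe" for totals strictly above 63 (the severe-fatigue cut-off).
#'
#' @param motor,cognitive Subscale scores, each in [10, 50].
#' @return List `total`, `severe` (vectorised).
#' @examples
#' score_fsmc(37.8, 37)  # total 74.8, severe
#' @export
score_fsmc <- function(motor, cognitive) {
  if (any(motor < 10 | motor > 50, na.rm = TRUE)) {
    stop_field("score_fsmc: motor subscale out of range [10, 50]")
  }
  if (any(cognitive < 10 | cognitive > 50, na.rm = TRUE)) {
    stop_field("score_fsmc: cognitive subscale out of range [10, 50]")
  }
  total <- motor + cognitive
  list(total = total, severe = total > 63)
}

#' Pearson correlation with two-sided t-based p-value
#'
#' r is the sample Pearson coefficient; the p-value comes from
#' t = r sqrt((n-2) / (1-r^2)) on n-2 degrees of freedom, two-sided
#' (delegated to [stats::cor.test()]). Pairs with missing values are dropped
#' pairwise. Zero variance in either argument yields a flagged undefined
#' result rather than propagating NaN.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List of class `correlation_result`: `n`, `r`, `p`, `defined`.
#' @export
pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop_field("pearson: need at least 3 complete pairs (got %d)", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(list(n = n, r = NA_real_, p = NA_real_, defined = FALSE),
                     class = "correlation_result"))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(n = n, r = unname(ct$estimate), p = ct$p.value, defined = TRUE),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("Pearson r = %.3f (n = %d, p = %.3g)\n", x$r, x$n, x$p))
  } else {
    cat(sprintf("Pearson correlation undefined (zero variance; n = %d)\n", x$n))
  }
  invisible(x)
}

#' Correlation analysis over declared variable pairs
#'
#' Runs [pearson()] for each requested pair, on the full cohort or the
#' patients-only subset, with pairwise-complete handling (each pair reports
#' its own n, so a subject missing one questionnaire drops only the pairs
#' that need it). Duplicate pair requests are de-duplicated; pairs with
#' fewer than 3 complete cases or zero variance are skipped with a warning.
#' No multiple-testing correction is applied by default (raw p-values are
#' reported); `adjust = "BH"` adds a Benjamini-Hochberg column.
#'
#' @param table Cohort data frame with a `group` column.
#' @param pairs Two-column matrix/data frame (or list of length-2 vectors) of
#'   variable names.
#' @param subset "all" or "patients".
#' @param adjust "none" or "BH".
#' @return Data frame `var1`, `var2`, `subset`, `n`, `r`, `p` (and `p_adj`).
#' @export
correlation_matrix <- function(table, pairs, subset = c("all", "patients"),
                               adjust = c("none", "BH")) {
  subset <- match.arg(subset)
  adjust <- match.arg(adjust)
  if (is.list(pairs) && !is.data.frame(pairs)) {
    pairs <- do.call(rbind, pairs)
  }
  pairs <- unique(as.data.frame(pairs, stringsAsFactors = FALSE))
  names(pairs) <- c("var1", "var2")
  df <- if (subset == "patients") table[table$group == "patient", ] else table
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    v1 <- pairs$var1[i]; v2 <- pairs$var2[i]
    for (v in c(v1, v2)) {
      if (!v %in% names(df)) stop_field("correlation_matrix: no column '%s'", v)
    }
    x <- df[[v1]]; y <- df[[v2]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) {
      warning(sprintf("pair (%s, %s): fewer than 3 complete cases; skipped", v1, v2),
              call. = FALSE)
      next
    }
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      warning(sprintf("pair (%s, %s): zero variance; skipped", v1, v2),
              call. = FALSE)
      next
    }
    pr <- pearson(x, y)
    out[[length(out) + 1L]] <- data.frame(
      var1 = v1, var2 = v2, subset = subset, n = pr$n, r = pr$r, p = pr$p,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(var1 = character(), var2 = character(),
                      subset = character(), n = integer(), r = numeric(),
                      p = numeric())
  }
  if (adjust == "BH" && nrow(res)) res$p_adj <- stats::p.adjust(res$p, "BH")
  rownames(res) <- NULL
  res
}

#' Generic two-group comparison (fold change, Student t, per-group CV)
#'
#' The comparison used for assay-level measures such as protein carbonyl
#' content or steroid panels: fold change = patient mean / control mean, a
#' two-sample Student (pooled-variance) t-test raw p, and each group's
#' coefficient of variation.
#'
#' @param values Numeric vector, one value per subject.
#' @param groups Character vector ("patient"/"control") aligned with
#'   `values`.
#' @return List `fc`, `p`, `cv_patient`, `cv_control`, `n_patient`,
#'   `n_control`. `fc` is flagged undefined (`NA`) when the control mean is
#'   not positive.
#' @export
group_compare <- function(values, groups) {
  pat <- values[groups == "patient" & is.finite(values)]
  ctl <- values[groups == "control" & is.finite(values)]
  if (length(pat) < 2 || length(ctl) < 2) {
    stop_field("group_compare: need >= 2 values per group")
  }
  tt <- two_group_t(pat, ctl)
  list(fc = if (mean(ctl) > 0) mean(pat) / mean(ctl) else NA_real_,
       p = tt$p.value,
       cv_patient = cv_of(pat), cv_control = cv_of(ctl),
       n_patient = length(pat), n_control = length(ctl))
}
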