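## ---- Targeted-metabolomics preprocessing and screen ----------------------
##
## Fixed pipeline order: qc_filter -> impute_min5 -> glog_transform ->
## pareto_scale; the fold-change screen runs on raw (pre-transform)
## concentrations, the t/FDR screen and PCA on the transformed/scaled matrix.

metab_sample_cols <- function(panel, groups) {
  miss <- setdiff(groups$subject, names(panel))
  if (length(miss)) stop_field("metabolite panel lacks sample column(s): %s",
                               paste(miss, collapse = ", "))
  groups$subject
}

qc_cols_of <- function(panel) grep("^QC", names(panel), value = TRUE)

#' Quality-control filter on a metabolite panel
#'
#' Drops compounds whose QC-replicate coefficient of variation exceeds
#' `max_qc_cv` or whose missing fraction across samples exceeds
#' `max_missing`. LC and FIA compounds are filtered independently (the
#' thresholds are applied per compound, so the platform split is preserved
#' and reported per platform). This is a deliberately simple two-rule
#' surrogate for full kit-QC software, and is labelled as such.
#'
#' @param panel Panel data frame (`compound`, `class`, `platform`, sample
#'   columns, `QC*` columns).
#' @param groups Sample-to-group map.
#' @param max_qc_cv Maximum allowed QC CV.
#' @param max_missing Maximum allowed per-compound missing fraction.
#' @return The filtered panel, with a `preprocess_report` attribute
#'   (`n_input`, `n_retained`, per-platform counts, missing fractions).
#' @export
qc_filter <- function(panel, groups, max_qc_cv = 0.25, max_missing = 0.3) {
  sc <- metab_sample_cols(panel, groups)
  qc <- qc_cols_of(panel)
  x <- as.matrix(panel[, sc])
  missing_frac <- rowMeans(is.na(x))
  if (!length(qc)) {
    warning("qc_filter: no QC columns present; QC-CV rule skipped", call. = FALSE)
    qccv <- rep(0, nrow(panel))
  } else {
    qccv <- apply(as.matrix(panel[, qc]), 1, cv_of)
  }
  keep <- qccv <= max_qc_cv & missing_frac <= max_missing
  out <- panel[keep, , drop = FALSE]
  rownames(out) <- NULL
  rep <- list(n_input = nrow(panel), n_retained = nrow(out),
              n_retained_by_platform = table(out$platform),
              missing_fraction_before = mean(is.na(x)),
              max_qc_cv = max_qc_cv, max_missing = max_missing)
  attr(out, "preprocess_report") <- rep
  out
}

#' Impute left-censored values with one fifth of the per-compound minimum
#'
#' Every missing cell of compound j is replaced by min(observed_j) / 5;
#' observed cells are untouched. Errors if a compound has no positive
#' observed value.
#'
#' @param panel Panel data frame.
#' @param groups Sample-to-group map.
#' @return The imputed panel; imputation constants in attribute
#'   `imputation_constants`.
#' @export
impute_min5 <- function(panel, groups) {
  sc <- metab_sample_cols(panel, groups)
  x <- as.matrix(panel[, sc])
  const <- rep(NA_real_, nrow(x))
  for (i in seq_len(nrow(x))) {
    obs <- x[i, ][is.finite(x[i, ]) & x[i, ] > 0]
    if (!length(obs)) {
      stop_field("impute_min5: compound '%s' has no positive observed value",
                 panel$compound[i])
    }
    const[i] <- min(obs) / 5
    x[i, is.na(x[i, ])] <- const[i]
  }
  panel[, sc] <- x
  attr(panel, "imputation_constants") <- stats::setNames(const, panel$compound)
  panel
}

#' Generalised-logarithm transform
#'
#' x -> log2((x + sqrt(x^2 + a^2)) / 2), a strictly increasing
#' variance-stabilising transform that behaves like log2(x) for x >> a and
#' stays finite at 0 (glog(0) = log2(a/2)).
#'
#' @param panel Panel data frame (imputed: no missing cells).
#' @param groups Sample-to-group map.
#' @param a Positive offset; default is the smallest positive value of the
#'   sample matrix divided by 10.
#' @return The transformed panel; `a` recorded in attribute `glog_a`.
#' @export
glog_transform <- function(panel, groups, a = NULL) {
  sc <- metab_sample_cols(panel, groups)
  x <- as.matrix(panel[, sc])
  if (anyNA(x)) stop_field("glog_transform: panel contains missing values; impute first")
  if (is.null(a)) a <- min(x[x > 0]) / 10
  if (!is.finite(a) || a <= 0) stop_field("glog_transform: offset 'a' must be > 0")
  panel[, sc] <- glog(x, a)
  attr(panel, "glog_a") <- a
  panel
}

#' @rdname glog_transform
#' @param x Numeric vector or matrix.
#' @export
glog <- function(x, a) log2((x + sqrt(x^2 + a^2)) / 2)

#' Pareto scaling
#'
#' Per compound (row): (x - mean) / sqrt(SD). Columns of the result have
#' mean 0 and SD equal to the square root of the original SD — an
#' intermediate between no scaling and unit-variance scaling that damps but
#' does not erase concentration-scale differences. Zero-variance compounds
#' are centred but left unscaled, with a warning.
#'
#' @param panel Panel data frame (transformed).
#' @param groups Sample-to-group map.
#' @return The scaled panel.
#' @export
pareto_scale <- function(panel, groups) {
  sc <- metab_sample_cols(panel, groups)
  x <- as.matrix(panel[, sc])
  for (i in seq_len(nrow(x))) {
    s <- stats::sd(x[i, ])
    if (s == 0) {
      warning(sprintf("pareto_scale: compound '%s' has zero variance; centred only",
                      panel$compound[i]), call. = FALSE)
      x[i, ] <- x[i, ] - mean(x[i, ])
    } else {
      x[i, ] <- (x[i, ] - mean(x[i, ])) / sqrt(s)
    }
  }
  panel[, sc] <- x
  panel
}

#' Fold-change screen on raw concentrations
#'
#' Flags compounds whose patient/control ratio of group means (computed on
#' raw, pre-transform concentrations) lies strictly outside
#' (`lower`, `upper`) — the printed convention "> 1.3 or < 0.77".
#'
#' @param panel Raw (or imputed) panel.
#' @param groups Sample-to-group map.
#' @param upper,lower Screen bounds (strict inequalities).
#' @return Data frame `compound`, `fc`, `flagged`.
#' @export
fc_screen <- function(panel, groups, upper = 1.3, lower = 0.77) {
  sc <- metab_sample_cols(panel, groups)
  pat <- sc[groups$group == "patient"]
  ctl <- sc[groups$group == "control"]
  x <- as.matrix(panel[, sc])
  fc <- rowMeans(x[, pat, drop = FALSE], na.rm = TRUE) /
    rowMeans(x[, ctl, drop = FALSE], na.rm = TRUE)
  data.frame(compound = panel$compound, fc = unname(fc),
             flagged = unname(fc > upper | fc < lower),
             stringsAsFactors = FALSE)
}

#' Per-compound t-test with Benjamini-Hochberg correction
#'
#' Two-sample Student t per compound on the transformed/scaled values, with
#' BH adjustment across compounds. Compounds significant at raw p < 0.05 but
#' not at the FDR level are labelled "nominal only".
#'
#' @param panel Transformed and scaled panel.
#' @param groups Sample-to-group map.
#' @param q FDR level.
#' @return Data frame `compound`, `p_raw`, `p_adj`, `significant`,
#'   `nominal_only`.
#' @export
t_fdr_screen <- function(panel, groups, q = 0.05) {
  sc <- metab_sample_cols(panel, groups)
  pat <- sc[groups$group == "patient"]
  ctl <- sc[groups$group == "control"]
  x <- as.matrix(panel[, sc])
  tt <- row_t_student(x, pat, ctl)
  p_adj <- stats::p.adjust(tt$p.value, method = "BH")
  data.frame(compound = panel$compound,
             p_raw = unname(tt$p.value), p_adj = unname(p_adj),
             significant = unname(p_adj < q),
             nominal_only = unname(tt$p.value < 0.05 & p_adj >= q),
             stringsAsFactors = FALSE)
}

#' Principal component analysis of the scaled panel
#'
#' Singular-value decomposition of the samples x compounds matrix (no
#' further centring or scaling: the panel is already Pareto-scaled per
#' compound).
#'
#' @param panel Scaled panel.
#' @param groups Sample-to-group map.
#' @param k Number of components (<= min(samples, compounds)).
#' @return List `scores` (samples x k), `loadings` (compounds x k,
#'   orthonormal), `explained_variance` (length-k fractions).
#' @export
metabolite_pca <- function(panel, groups, k = 2) {
  sc <- metab_sample_cols(panel, groups)
  x <- t(as.matrix(panel[, sc]))           # samples x compounds
  colnames(x) <- panel$compound
  if (k > min(dim(x))) stop_field("metabolite_pca: k = %d exceeds min(samples, compounds) = %d",
                                  k, min(dim(x)))
  sv <- svd(x, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  rownames(scores) <- rownames(x)
  loadings <- sv$v
  rownames(loadings) <- colnames(x)
  ev <- sv$d^2 / sum(svd(x)$d^2)
  list(scores = scores, loadings = loadings,
       explained_variance = ev[seq_len(k)])
}

#' Run the full metabolomics preprocessing + screen pipeline
#'
#' qc_filter -> impute_min5 -> glog_transform -> pareto_scale, then the
#' fold-change screen on raw concentrations and the t/FDR screen and PCA on
#' the scaled matrix.
#'
#' @param panel Raw panel.
#' @param groups Sample-to-group map.
#' @param max_qc_cv,max_missing QC-filter thresholds.
#' @param glog_a Optional glog offset.
#' @param fc_upper,fc_lower Fold-change screen bounds.
#' @param q FDR level.
#' @return Object of class `metabolite_screen`: list with `report`,
#'   `fc_results`, `t_results`, `pca`, `panel_scaled`.
#' @export
metabolomics_pipeline <- function(panel, groups, max_qc_cv = 0.25,
                                  max_missing = 0.3, glog_a = NULL,
                                  fc_upper = 1.3, fc_lower = 0.77, q = 0.05) {
  filtered <- qc_filter(panel, groups, max_qc_cv, max_missing)
  report <- attr(filtered, "preprocess_report")
  imputed <- impute_min5(filtered, groups)
  report$missing_fraction_after <- 0
  report$imputation_constants <- attr(imputed, "imputation_constants")
  transformed <- glog_transform(imputed, groups, a = glog_a)
  report$glog_a <- attr(transformed, "glog_a")
  scaled <- pareto_scale(transformed, groups)
  fc_res <- fc_screen(imputed, groups, upper = fc_upper, lower = fc_lower)
  t_res <- t_fdr_screen(scaled, groups, q = q)
  pca <- metabolite_pca(scaled, groups,
                        k = min(2, length(groups$subject) - 1, nrow(scaled)))
  structure(list(report = report, fc_results = fc_res, t_results = t_res,
                 pca = pca, panel_scaled = scaled),
            class = "metabolite_screen")
}

#' @export
print.metabolite_screen <- function(x, ...) {
  cat(sprintf("Metabolomics screen: %d/%d compounds retained; %d outside FC bounds; %d FDR-significant (%d nominal only)\n",
              x$report$n_retained, x$report$n_input,
              sum(x$fc_results$flagged), sum(x$t_results$significant),
              sum(x$t_results$nominal_only)))
  invisible(x)
}
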