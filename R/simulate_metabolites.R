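#' Simulate a targeted-metabolomics panel
#'
#' Draws per-compound log-normal concentrations for every subject, with
#' left-censoring below a per-compound limit of detection (LOD): each
#' compound's LOD is placed at the `missing_rate` quantile of its true
#' concentration distribution, so every cell is censored (recorded missing)
#' with probability `missing_rate` — a missing-not-at-random mechanism that
#' matches how targeted kits censor at LOD. Compounds are labelled by
#' acquisition platform (42 LC, remainder FIA for the default 408-compound
#' panel, scaled proportionally otherwise) and carry three QC replicate
#' columns with CV `qc_cv`.
#'
#' @param spec A [cohort_spec()].
#' @return List of class `synthetic_metabolites` with `panel` (data frame:
#'   `compound`, `class`, `platform`, one concentration column per sample,
#'   `QC1`..`QC3`), `groups`, and `lod` (per-compound detection limits).
#' @export
simulate_metabolite_table <- function(spec) {
  validate_cohort_spec(spec)
  subj <- subject_ids(spec)
  n <- spec$n_metabolites
  with_seed(spec$seed, 303L, {
    n_lc <- max(1L, round(n * 42 / 408))
    platform <- rep(c("LC", "FIA"), c(n_lc, n - n_lc))
    classes <- c("acylcarnitine", "aminoacid", "biogenic_amine",
                 "glycerophospholipid", "sphingolipid", "sugar")
    compound <- sprintf("M%03d_%s", seq_len(n), platform)
    cls <- sample(classes, n, replace = TRUE)

    mu <- stats::rlnorm(n, meanlog = log(50), sdlog = 1)   # µmol/L scale
    sdlog <- sqrt(log(1 + spec$metab_cv^2))
    meanlog <- log(mu) - sdlog^2 / 2
    lod <- if (spec$missing_rate > 0) {
      stats::qlnorm(spec$missing_rate, meanlog, sdlog)
    } else rep(0, n)

    conc <- matrix(stats::rlnorm(n * nrow(subj), meanlog, sdlog),
                   nrow = n, dimnames = list(compound, subj$subject))
    conc[conc < lod] <- NA_real_
    qc <- matrix(rlnorm_cv(n * 3, 1, spec$qc_cv) * mu,
                 nrow = n, dimnames = list(compound, c("QC1", "QC2", "QC3")))

    panel <- data.frame(compound = compound, class = cls, platform = platform,
                        stringsAsFactors = FALSE)
    panel <- cbind(panel, as.data.frame(conc), as.data.frame(qc))
    rownames(panel) <- NULL
    structure(list(panel = panel, groups = subj, lod = lod, spec = spec),
              class = "synthetic_metabolites")
  })
}

#' @export
print.synthetic_metabolites <- function(x, ...) {
  sc <- x$groups$subject
  miss <- mean(is.na(as.matrix(x$panel[, sc])))
  cat(sprintf("Synthetic metabolite panel: %d compounds x %d samples (%.2f%% missing)\n",
              nrow(x$panel), length(sc), 100 * miss))
  invisible(x)
}
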