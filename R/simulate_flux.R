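## Default "true" section means for a healthy control well, chosen to give a
## textbook PBMC stress-test profile: basal OCR 100 pmol O2/min with a
## non-mitochondrial floor of 20 (so basal mitochondrial respiration 80),
## ATP-linked fraction 0.75 (coupling efficiency 75%), FCCP-uncoupled OCR 180
## (spare capacity 2.0); basal ECAR 20 mpH/min with a non-glycolytic floor of
## 8 and an oligomycin-stimulated glycolytic capacity of 27.
flux_baseline <- function() {
  list(
    ocr_basal = 100, ocr_nonmito = 20, ocr_fccp = 180,
    atp_fraction = 0.75,
    ecar_basal = 20, ecar_nonglyco = 8, ecar_oligo = 35,
    ## OCR in the glycolysis-scheme wells after oligomycin / 2-DG, and ECAR
    ## drift in the respiration-scheme wells: realistic but unused by the
    ## default 14-parameter set.
    ocr_c_oligo = 40, ocr_c_2dg = 42,
    ecar_after_oligo_a = 30, ecar_after_rotaa = 25, ecar_after_fccp = 24
  )
}

#' Simulate an extracellular-flux plate with known ground truth
#'
#' Emits per-well OCR/ECAR measurement cycles for the three-scheme injection
#' design: scheme A (oligomycin, then rotenone/antimycin A), scheme B (FCCP,
#' then rotenone/antimycin A) and scheme C (oligomycin, then 2-deoxy-D-glucose,
#' read on the ECAR channel). Each subject receives
#' `wells_per_subject_per_scheme` replicate wells per scheme, each with three
#' sections (basal, inj1, inj2) of three measurement cycles. Well values are
#' the subject's true section mean times multiplicative log-normal noise with
#' coefficient of variation `noise_cv`. Patients' true ATP-linked fraction of
#' basal mitochondrial respiration is scaled by `coupling_effect`, so the
#' induced group coupling-efficiency fold change equals `coupling_effect` in
#' expectation.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `synthetic_flux` with elements `plate` (a
#'   [flux_plate()]), and `truth` (a data frame of per-subject true section
#'   means, ATP-linked fractions and magnitudes).
#' @examples
#' sim <- simulate_flux_plate(cohort_spec(seed = 1, wells_per_subject_per_scheme = 2))
#' head(sim$plate$traces)
#' @export
simulate_flux_plate <- function(spec) {
  validate_cohort_spec(spec)
  base <- flux_baseline()
  subj <- subject_ids(spec)
  n <- nrow(subj)
  with_seed(spec$seed, 101L, {
    magnitude <- rlnorm_cv(n, 1, spec$subject_cv)
    effect <- ifelse(subj$group == "patient", spec$coupling_effect, 1)
    atp_frac <- base$atp_fraction * effect +
      stats::rnorm(n, 0, spec$coupling_sd)
    atp_frac <- pmin(pmax(atp_frac, 0.05), 0.98)

    truth <- data.frame(
      subject = subj$subject, group = subj$group,
      magnitude = magnitude, atp_fraction = atp_frac,
      stringsAsFactors = FALSE
    )
    ## true section means per subject (scheme x section x signal)
    truth$ocr_basal    <- base$ocr_basal * magnitude
    truth$ocr_nonmito  <- base$ocr_nonmito * magnitude
    truth$ocr_oligo    <- truth$ocr_basal -
      atp_frac * (truth$ocr_basal - truth$ocr_nonmito)
    truth$ocr_fccp     <- base$ocr_fccp * magnitude
    truth$ecar_basal   <- base$ecar_basal * magnitude
    truth$ecar_oligo   <- base$ecar_oligo * magnitude
    truth$ecar_nonglyco <- base$ecar_nonglyco * magnitude

    schemes <- c("A", "B", "C")
    sections <- c("basal", "inj1", "inj2")
    w <- spec$wells_per_subject_per_scheme
    ncycle <- 3L

    grid <- expand.grid(cycle = seq_len(ncycle), section = sections,
                        rep = seq_len(w), scheme = schemes,
                        si = seq_len(n), stringsAsFactors = FALSE)
    grid$subject <- subj$subject[grid$si]
    grid$group <- subj$group[grid$si]
    grid$well <- sprintf("W%04d",
                         as.integer(factor(paste(grid$si, grid$scheme, grid$rep),
                                           levels = unique(paste(grid$si, grid$scheme, grid$rep)))))

    sec_mean <- function(signal) {
      key <- paste(grid$scheme, grid$section, signal)
      lookup <- c(
        "A basal ocr" = "ocr_basal",  "A inj1 ocr" = "ocr_oligo",
        "A inj2 ocr" = "ocr_nonmito",
        "B basal ocr" = "ocr_basal",  "B inj1 ocr" = "ocr_fccp",
        "B inj2 ocr" = "ocr_nonmito",
        "C basal ocr" = "ocr_basal",  "C inj1 ocr" = NA, "C inj2 ocr" = NA,
        "A basal ecar" = "ecar_basal", "A inj1 ecar" = NA, "A inj2 ecar" = NA,
        "B basal ecar" = "ecar_basal", "B inj1 ecar" = NA, "B inj2 ecar" = NA,
        "C basal ecar" = "ecar_basal", "C inj1 ecar" = "ecar_oligo",
        "C inj2 ecar" = "ecar_nonglyco"
      )
      out <- numeric(nrow(grid))
      for (k in unique(key)) {
        idx <- key == k
        col <- lookup[[k]]
        if (!is.na(col)) {
          out[idx] <- truth[[col]][grid$si[idx]]
        } else {
          fixed <- switch(k,
            "C inj1 ocr" = base$ocr_c_oligo,
            "C inj2 ocr" = base$ocr_c_2dg,
            "A inj1 ecar" = base$ecar_after_oligo_a,
            "A inj2 ecar" = base$ecar_after_rotaa,
            "B inj1 ecar" = base$ecar_after_fccp,
            "B inj2 ecar" = base$ecar_after_rotaa)
          out[idx] <- fixed * truth$magnitude[grid$si[idx]]
        }
      }
      out
    }

    m <- nrow(grid)
    grid$ocr <- sec_mean("ocr") * noise_factors(m, spec$noise_cv)
    grid$ecar <- sec_mean("ecar") * noise_factors(m, spec$noise_cv)

    traces <- grid[, c("well", "subject", "group", "scheme", "section",
                       "cycle", "ocr", "ecar")]
    rownames(traces) <- NULL
    layout <- unique(grid[, c("well", "subject", "group", "scheme")])
    rownames(layout) <- NULL

    structure(
      list(plate = flux_plate(traces, layout), truth = truth, spec = spec),
      class = "synthetic_flux"
    )
  })
}

#' @export
print.synthetic_flux <- function(x, ...) {
  cat(sprintf("Synthetic flux plate: %d wells, %d subjects, %d trace rows\n",
              nrow(x$plate$layout), nrow(x$truth), nrow(x$plate$traces)))
  invisible(x)
}
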