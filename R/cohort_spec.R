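#' Specification of a synthetic case-control cohort
#'
#' Bundles every knob of the synthetic-data generators: cohort size, the
#' group-level coupling-efficiency effect on patients, well-level measurement
#' noise, proteomics spike design, metabolite missingness and the target
#' questionnaire/severity correlation. The defaults mirror the study design
#' the package emulates: 6 patients and 4 age- and gender-matched controls,
#' a patient-vs-control coupling-efficiency fold change of 0.87, and
#' fold-change spikes straddling the control-CV-derived thresholds.
#'
#' @param n_patients,n_controls Subjects per group (>= 1).
#' @param seed Integer seed; all four generators are deterministic given the
#'   spec (each draws from its own stream derived from this seed).
#' @param coupling_effect Multiplicative factor applied to patients' true
#'   ATP-linked fraction of basal mitochondrial respiration, so the induced
#'   group coupling-efficiency fold change equals this value in expectation.
#'   Must be > 0; 1 means no group effect.
#' @param wells_per_subject_per_scheme Replicate wells per subject for each of
#'   the three injection schemes. The study does not report its replicate
#'   count; 8 is a plausible plate layout and is fully configurable.
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   well-level measurement noise (>= 0).
#' @param subject_cv CV of between-subject variation in overall metabolic
#'   rate magnitude (scales a subject's OCR and ECAR jointly).
#' @param coupling_sd Between-subject SD of the ATP-linked fraction, on the
#'   fraction scale (biological variation in coupling efficiency).
#' @param n_proteins Number of proteins in the synthetic quantification table.
#' @param n_dap_up,n_dap_down Numbers of proteins spiked up/down in patients.
#' @param dap_fc_up,dap_fc_down Spiked fold changes (> 1 and in (0,1)).
#' @param protein_cv CV of channel-level protein measurement noise. The
#'   default 0.06 makes the median control CV, and hence the derived
#'   fold-change thresholds, land near the 1.12 / 0.89 pair used in the study.
#' @param frac_mito Fraction of proteins flagged mitochondrial.
#' @param frac_lowinfo Fraction of proteins drawn with too few unique peptides
#'   or quantitative scans, so the inclusion filter has work to do.
#' @param n_metabolites Number of compounds on the synthetic panel. The
#'   default mirrors a Biocrates-style panel of 408 compounds, 42 acquired by
#'   LC and the rest by flow-injection analysis.
#' @param missing_rate Per-cell probability of left-censoring below the
#'   limit of detection, in [0, 1).
#' @param qc_cv CV of the triplicate QC-sample replicates.
#' @param metab_cv CV of between-sample metabolite variation.
#' @param questionnaire_corr Target Pearson correlation between the latent
#'   severity and each questionnaire instrument, |r| < 1. Instruments keyed
#'   to ill-health (FSMC, COMPASS-31) load positively, SF-36 domains
#'   negatively.
#'
#' @return An object of class `cohort_spec` (a validated list).
#' @examples
#' spec <- cohort_spec(seed = 1)
#' spec$n_patients
#' @export
cohort_spec <- function(n_patients = 6L,
                        n_controls = 4L,
                        seed = 1L,
                        coupling_effect = 0.87,
                        wells_per_subject_per_scheme = 8L,
                        noise_cv = 0.05,
                        subject_cv = 0.08,
                        coupling_sd = 0.02,
                        n_proteins = 3300L,
                        n_dap_up = 13L,
                        n_dap_down = 9L,
                        dap_fc_up = 1.5,
                        dap_fc_down = 0.7,
                        protein_cv = 0.06,
                        frac_mito = 0.085,
                        frac_lowinfo = 0.1,
                        n_metabolites = 408L,
                        missing_rate = 0.012,
                        qc_cv = 0.1,
                        metab_cv = 0.25,
                        questionnaire_corr = 0.93) {
  spec <- list(
    n_patients = as.integer(n_patients),
    n_controls = as.integer(n_controls),
    seed = as.integer(seed),
    coupling_effect = coupling_effect,
    wells_per_subject_per_scheme = as.integer(wells_per_subject_per_scheme),
    noise_cv = noise_cv,
    subject_cv = subject_cv,
    coupling_sd = coupling_sd,
    n_proteins = as.integer(n_proteins),
    n_dap_up = as.integer(n_dap_up),
    n_dap_down = as.integer(n_dap_down),
    dap_fc_up = dap_fc_up,
    dap_fc_down = dap_fc_down,
    protein_cv = protein_cv,
    frac_mito = frac_mito,
    frac_lowinfo = frac_lowinfo,
    n_metabolites = as.integer(n_metabolites),
    missing_rate = missing_rate,
    qc_cv = qc_cv,
    metab_cv = metab_cv,
    questionnaire_corr = questionnaire_corr
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
}

#' @rdname cohort_spec
#' @param spec A `cohort_spec` to validate.
#' @export
validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  pos_counts <- c("n_patients", "n_controls", "wells_per_subject_per_scheme",
                  "n_proteins", "n_metabolites")
  for (f in pos_counts) {
    if (!is.finite(spec[[f]]) || spec[[f]] < 1) {
      stop_field("cohort_spec: field '%s' must be a count >= 1 (got %s)",
                 f, format(spec[[f]]))
    }
  }
  for (f in c("n_dap_up", "n_dap_down")) {
    if (!is.finite(spec[[f]]) || spec[[f]] < 0) {
      stop_field("cohort_spec: field '%s' must be a count >= 0 (got %s)",
                 f, format(spec[[f]]))
    }
  }
  if (spec$noise_cv < 0) stop_field("cohort_spec: field 'noise_cv' must be >= 0")
  if (spec$subject_cv < 0) stop_field("cohort_spec: field 'subject_cv' must be >= 0")
  if (spec$coupling_effect <= 0) {
    stop_field("cohort_spec: field 'coupling_effect' must be > 0")
  }
  if (spec$missing_rate < 0 || spec$missing_rate >= 1) {
    stop_field("cohort_spec: field 'missing_rate' must lie in [0, 1)")
  }
  if (spec$dap_fc_up <= 1) stop_field("cohort_spec: field 'dap_fc_up' must be > 1")
  if (spec$dap_fc_down <= 0 || spec$dap_fc_down >= 1) {
    stop_field("cohort_spec: field 'dap_fc_down' must lie in (0, 1)")
  }
  if (spec$n_dap_up + spec$n_dap_down > spec$n_proteins) {
    stop_field("cohort_spec: spiked proteins (n_dap_up + n_dap_down = %d) exceed n_proteins = %d",
               spec$n_dap_up + spec$n_dap_down, spec$n_proteins)
  }
  if (abs(spec$questionnaire_corr) >= 1) {
    stop_field("cohort_spec: field 'questionnaire_corr' must satisfy |r| < 1")
  }
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat(sprintf("  subjects: %d patients / %d controls (seed %d)\n",
              x$n_patients, x$n_controls, x$seed))
  cat(sprintf("  flux: coupling effect %.3g, %d wells/subject/scheme, noise CV %.3g\n",
              x$coupling_effect, x$wells_per_subject_per_scheme, x$noise_cv))
  cat(sprintf("  proteins: %d (%d up @ FC %.3g, %d down @ FC %.3g)\n",
              x$n_proteins, x$n_dap_up, x$dap_fc_up, x$n_dap_down, x$dap_fc_down))
  cat(sprintf("  metabolites: %d, missing rate %.3g\n",
              x$n_metabolites, x$missing_rate))
  cat(sprintf("  questionnaire correlation target: %.3g\n", x$questionnaire_corr))
  invisible(x)
}

subject_ids <- function(spec) {
  data.frame(
    subject = c(sprintf("P%02d", seq_len(spec$n_patients)),
                sprintf("C%02d", seq_len(spec$n_controls))),
    group = rep(c("patient", "control"), c(spec$n_patients, spec$n_controls)),
    stringsAsFactors = FALSE
  )
}
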