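#' Simulate a full synthetic cohort across all four data layers
#'
#' Runs the flux-plate, protein-table, metabolite-panel and questionnaire
#' generators for one [cohort_spec()]. Each generator draws from its own
#' seed stream derived from `spec$seed`, so layers are individually
#' reproducible and adding one layer never perturbs another.
#'
#' @param spec A [cohort_spec()].
#' @return List of class `synthetic_cohort`: `flux`, `proteins`,
#'   `metabolites`, `questionnaires`, `spec`.
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  validate_cohort_spec(spec)
  structure(list(flux = simulate_flux_plate(spec),
                 proteins = simulate_protein_table(spec),
                 metabolites = simulate_metabolite_table(spec),
                 questionnaires = simulate_questionnaires(spec),
                 spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort (seed", x$spec$seed, ")\n")
  print(x$flux); print(x$proteins); print(x$metabolites); print(x$questionnaires)
  invisible(x)
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Emits `flux_traces.csv`, `flux_layout.csv`, `protein_table.tsv`,
#' `sample_groups.csv`, `metabolite_panel.csv`, `cohort.csv`, and a
#' `ground_truth.json` sidecar holding the cohort specification (including
#' its seed), the
#' per-subject flux truth, spiked protein identities and latent severities.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_flux_plate(cohort$flux$plate, p("flux_traces.csv"), p("flux_layout.csv"))
  utils::write.table(cohort$proteins$table, p("protein_table.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$proteins$groups, p("sample_groups.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$metabolites$panel, p("metabolite_panel.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$questionnaires$table, p("cohort.csv"),
                   row.names = FALSE, quote = FALSE)
  truth <- list(
    spec = unclass(cohort$spec),
    flux_truth = cohort$flux$truth,
    spiked_proteins = cohort$proteins$truth[cohort$proteins$truth$spiked, ],
    severity = cohort$questionnaires$truth,
    run_log = cohort$questionnaires$run_log
  )
  jsonlite::write_json(truth, p("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(vapply(c("flux_traces.csv", "flux_layout.csv", "protein_table.tsv",
                     "sample_groups.csv", "metabolite_panel.csv", "cohort.csv",
                     "ground_truth.json"), p, character(1)))
}
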