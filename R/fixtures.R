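#' Packaged reference DAP table
#'
#' The 22-protein differentially-altered-protein list (accession, description,
#' gene, printed fold change and raw p) packaged as a plain-text fixture, as
#' published: 13 proteins increased and 9 decreased in patients. Used by the
#' examples and acceptance checks to exercise the DAP classification on known
#' input.
#'
#' @return Data frame with columns `accession`, `description`, `gene`, `fc`,
#'   `p_raw`.
#' @examples
#' ref <- dap_reference_table()
#' nrow(ref)  # 22
#' @export
dap_reference_table <- function() {
  utils::read.delim(mecfsomics_extdata("dap_reference.tsv"),
                    stringsAsFactors = FALSE)
}

#' Packaged questionnaire group summaries
#'
#' Group-level means and SDs (controls vs patients) for the FSMC subscales
#' and total, the SF-36 domains and the COMPASS-31 weighted score, as
#' reported for the cohort the synthetic generator emulates.
#'
#' @return Data frame `instrument`, `control_mean`, `control_sd`,
#'   `patient_mean`, `patient_sd`.
#' @export
questionnaire_reference_table <- function() {
  utils::read.delim(mecfsomics_extdata("questionnaire_reference.tsv"),
                    stringsAsFactors = FALSE)
}
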