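#' Simulate a TMT-style protein quantification table
#'
#' Draws log-normal baseline abundances per protein, multiplies patients'
#' channels by the spiked fold changes for `n_dap_up` + `n_dap_down`
#' differential proteins, and applies channel-level multiplicative log-normal
#' noise with CV `protein_cv`. Unique-peptide and quantitative-scan counts
#' are drawn so roughly `frac_lowinfo` of proteins fail the inclusion filter
#' (>= 2 unique peptides and >= 5 quantitative scans); a fraction `frac_mito`
#' is flagged mitochondrial. Spiked proteins always carry enough peptide
#' support to survive the filter, so ground-truth recovery is well defined.
#'
#' @param spec A [cohort_spec()].
#' @return List of class `synthetic_proteins` with `table` (a data frame:
#'   `accession`, `gene`, `unique_peptides`, `quant_scans`, `mitochondrial`,
#'   one abundance column per sample), `groups` (sample to group map) and
#'   `truth` (accessions with true fold changes).
#' @export
simulate_protein_table <- function(spec) {
  validate_cohort_spec(spec)
  subj <- subject_ids(spec)
  n <- spec$n_proteins
  with_seed(spec$seed, 202L, {
    accession <- sprintf("SYN%05d", seq_len(n))
    gene <- sprintf("GENE%05d", seq_len(n))
    ## spike positions drawn at random so spiked rows are not clustered
    perm <- sample.int(n)
    true_fc <- rep(1, n)
    if (spec$n_dap_up > 0) true_fc[perm[seq_len(spec$n_dap_up)]] <- spec$dap_fc_up
    if (spec$n_dap_down > 0) {
      true_fc[perm[spec$n_dap_up + seq_len(spec$n_dap_down)]] <- spec$dap_fc_down
    }

    baseline <- stats::rlnorm(n, meanlog = log(1e6), sdlog = 1)
    spiked <- true_fc != 1
    ## peptide support: low-information proteins get 1 peptide or < 5 scans
    lowinfo <- stats::runif(n) < spec$frac_lowinfo & !spiked
    unique_peptides <- ifelse(lowinfo, 1L, 2L + stats::rpois(n, 4))
    quant_scans <- ifelse(lowinfo,
                          pmax(1L, stats::rpois(n, 3)),
                          5L + stats::rpois(n, 15))
    mitochondrial <- stats::runif(n) < spec$frac_mito

    abund <- matrix(0, nrow = n, ncol = nrow(subj),
                    dimnames = list(accession, subj$subject))
    for (j in seq_len(nrow(subj))) {
      mu <- baseline * (if (subj$group[j] == "patient") true_fc else 1)
      abund[, j] <- mu * noise_factors(n, spec$protein_cv)
    }

    tab <- data.frame(accession = accession, gene = gene,
                      unique_peptides = unique_peptides,
                      quant_scans = quant_scans,
                      mitochondrial = mitochondrial,
                      stringsAsFactors = FALSE)
    tab <- cbind(tab, as.data.frame(abund))
    truth <- data.frame(accession = accession, gene = gene, true_fc = true_fc,
                        spiked = spiked, stringsAsFactors = FALSE)
    structure(list(table = tab, groups = subj, truth = truth, spec = spec),
              class = "synthetic_proteins")
  })
}

#' @export
print.synthetic_proteins <- function(x, ...) {
  cat(sprintf("Synthetic protein table: %d proteins x %d samples (%d spiked)\n",
              nrow(x$table), nrow(x$groups), sum(x$truth$spiked)))
  invisible(x)
}
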