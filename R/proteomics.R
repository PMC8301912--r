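## ---- Differential protein-abundance screen -------------------------------
##
## Inclusion filter -> control-CV-derived fold-change thresholds -> per-protein
## fold change + Student t on log2 abundances -> DAP classification and the
## mitochondrial / pathway / CD-marker summaries.

protein_sample_cols <- function(table, groups) {
  miss <- setdiff(groups$subject, names(table))
  if (length(miss)) {
    stop_field("protein table lacks abundance column(s): %s",
               paste(miss, collapse = ", "))
  }
  groups$subject
}

#' Inclusion filter on peptide and scan support
#'
#' Retains proteins with at least `min_peptides` unique peptides and
#' `min_scans` quantitative scans (both bounds inclusive). Idempotent.
#'
#' @param table Protein table with `unique_peptides` and `quant_scans`.
#' @param min_peptides,min_scans Minimum support counts (defaults 2 and 5).
#' @return The filtered table; the number of removed rows is reported via
#'   `message()` and attached as attribute `n_removed`.
#' @export
filter_quantifiable <- function(table, min_peptides = 2L, min_scans = 5L) {
  stopifnot(min_peptides >= 0, min_scans >= 0)
  keep <- table$unique_peptides >= min_peptides & table$quant_scans >= min_scans
  removed <- sum(!keep)
  if (removed > 0) {
    message(sprintf("filter_quantifiable: removed %d of %d proteins below support thresholds",
                    removed, nrow(table)))
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- removed
  out
}

#' Derive fold-change thresholds from control-group variability
#'
#' Computes each protein's coefficient of variation (SD / mean) over the
#' control samples and sets the upper fold-change threshold to
#' 1 + 2 x median(CV), with the lower threshold as its reciprocal. With a
#' median control CV of 0.06 this yields the familiar 1.12 / 0.89 pair
#' (1/1.12 = 0.893 prints as 0.89). Full precision is kept for
#' classification; rounding is display-only.
#'
#' @param table Protein table (abundance columns as in `groups`).
#' @param groups Data frame `subject`, `group`; at least 2 control samples.
#' @param symmetric Use 1 - 2 x median(CV) for the lower threshold instead of
#'   the reciprocal.
#' @return Object of class `fc_thresholds`: list with `upper`, `lower`,
#'   `source_median_cv`.
#' @export
derive_fc_thresholds <- function(table, groups, symmetric = FALSE) {
  cols <- protein_sample_cols(table, groups)
  ctl <- cols[groups$group == "control"]
  if (length(ctl) < 2) stop_field("derive_fc_thresholds: need >= 2 control samples")
  m <- as.matrix(table[, ctl, drop = FALSE])
  cvs <- apply(m, 1, cv_of)
  med <- stats::median(cvs, na.rm = TRUE)
  upper <- 1 + 2 * med
  lower <- if (symmetric) 1 - 2 * med else 1 / upper
  if (med == 0) warning("derive_fc_thresholds: median control CV is 0; degenerate thresholds (1, 1)",
                        call. = FALSE)
  structure(list(upper = upper, lower = lower, source_median_cv = med),
            class = "fc_thresholds")
}

#' @export
print.fc_thresholds <- function(x, ...) {
  cat(sprintf("Fold-change thresholds: > %.2f or < %.2f (median control CV %.4f)\n",
              x$upper, x$lower, x$source_median_cv))
  invisible(x)
}

#' Per-protein differential test
#'
#' For every protein: fold change = mean(patient abundances) / mean(control
#' abundances) on the linear scale, and a two-sample Student (pooled-variance)
#' t-test on log2 abundances. A protein is a differentially altered protein
#' (DAP) when it passes both criteria: fc >= `thresholds$upper` or
#' fc <= `thresholds$lower` (inclusive, at full precision) and raw p <
#' `alpha`.
#'
#' @param table Protein table (ideally pre-filtered by
#'   [filter_quantifiable()]).
#' @param groups Sample-to-group map (`subject`, `group`).
#' @param thresholds An `fc_thresholds` object (or list with upper/lower).
#' @param alpha Significance level for the raw p criterion.
#' @return Object of class `dap_screen`: data frame `accession`, `gene`,
#'   `fc`, `p_raw`, `passes_fc`, `passes_p`, `is_dap`, `direction`, plus the
#'   thresholds as an attribute.
#' @export
test_proteins <- function(table, groups, thresholds, alpha = 0.05) {
  cols <- protein_sample_cols(table, groups)
  pat <- cols[groups$group == "patient"]
  ctl <- cols[groups$group == "control"]
  if (length(pat) < 2 || length(ctl) < 2) {
    stop_field("test_proteins: need >= 2 samples per group")
  }
  m <- as.matrix(table[, cols, drop = FALSE])
  tt <- row_t_student(log2(m), pat, ctl)
  fc <- rowMeans(m[, pat, drop = FALSE]) / rowMeans(m[, ctl, drop = FALSE])
  res <- data.frame(
    accession = table$accession,
    gene = if ("gene" %in% names(table)) table$gene else NA_character_,
    fc = unname(fc),
    p_raw = unname(tt$p.value),
    stringsAsFactors = FALSE
  )
  classify_results(res, thresholds, alpha)
}

## Attach pass/direction flags to a (fc, p_raw) results table.
classify_results <- function(res, thresholds, alpha = 0.05) {
  res$passes_fc <- res$fc >= thresholds$upper | res$fc <= thresholds$lower
  res$passes_p <- res$p_raw < alpha
  res$is_dap <- res$passes_fc & res$passes_p
  res$direction <- ifelse(!res$is_dap, "none",
                          ifelse(res$fc >= thresholds$upper, "up", "down"))
  attr(res, "thresholds") <- thresholds
  attr(res, "alpha") <- alpha
  class(res) <- c("dap_screen", "data.frame")
  res
}

#' Summarise differentially altered proteins
#'
#' @param results A `dap_screen` (from [test_proteins()]) or any data frame
#'   with `fc` and `p_raw` columns, e.g. the packaged reference DAP table.
#' @param thresholds Optional `fc_thresholds`; defaults to those attached to
#'   `results`.
#' @param alpha Raw-p criterion.
#' @return List of class `dap_summary`: `n_total`, `n_up`, `n_down`, and
#'   `daps` (the DAP rows sorted by ascending raw p).
#' @export
classify_daps <- function(results, thresholds = attr(results, "thresholds"),
                          alpha = attr(results, "alpha") %||% 0.05) {
  if (is.null(thresholds)) stop_field("classify_daps: thresholds required")
  res <- classify_results(as.data.frame(results)[, c("accession", "gene", "fc", "p_raw")],
                          thresholds, alpha)
  daps <- res[res$is_dap, ]
  daps <- daps[order(daps$p_raw), ]
  rownames(daps) <- NULL
  structure(list(n_total = sum(res$is_dap),
                 n_up = sum(res$direction == "up"),
                 n_down = sum(res$direction == "down"),
                 daps = daps, thresholds = thresholds, alpha = alpha),
            class = "dap_summary")
}

#' @export
print.dap_summary <- function(x, ...) {
  cat(sprintf("DAPs: %d total (%d increased, %d decreased) at FC >= %.4f / <= %.4f, p < %g\n",
              x$n_total, x$n_up, x$n_down,
              x$thresholds$upper, x$thresholds$lower, x$alpha))
  if (x$n_total) print.data.frame(utils::head(x$daps, 10), digits = 3)
  invisible(x)
}

#' Mitochondrial subset summary
#'
#' Restricts screen results to proteins whose gene is on a mitochondrial gene
#' list (MitoCarta-style) and reports the subset size and the median fold
#' change — near 1 when total mitochondrial protein content is unchanged.
#'
#' @param results Screen results with `gene` and `fc`.
#' @param mito_genes Character vector of mitochondrial gene symbols, or a
#'   path to a text file with one symbol per line (see [read_gene_list()]).
#' @return List: `n_mito`, `median_fc`, `table` (the matching rows).
#' @export
mito_summary <- function(results, mito_genes = mecfsomics_extdata("mito_genes_example.txt")) {
  if (is.character(mito_genes) && length(mito_genes) == 1 &&
      (file.exists(mito_genes) || grepl("[/\\\\]", mito_genes))) {
    mito_genes <- read_gene_list(mito_genes)
  }
  sub <- as.data.frame(results)[results$gene %in% mito_genes, ]
  if (!nrow(sub)) {
    warning("mito_summary: no screened protein matches the mitochondrial list",
            call. = FALSE)
    return(list(n_mito = 0L, median_fc = NA_real_, table = sub))
  }
  list(n_mito = nrow(sub), median_fc = stats::median(sub$fc), table = sub)
}

#' Pathway-level group test
#'
#' One-sample Student t-test of the member proteins' log2 fold changes
#' against 0, per pathway. Pathways with fewer than two members with a
#' defined fold change are skipped with a warning. Member sets whose log2
#' fold changes are all (numerically) zero carry no evidence of a shift and
#' return p = 1.
#'
#' @param results Screen results with `gene` and `fc`.
#' @param pathways Named list of gene-symbol vectors, or a data frame with
#'   columns `pathway`, `gene`.
#' @return Data frame `pathway`, `n_genes`, `mean_log2fc`, `p`.
#' @export
pathway_group_test <- function(results, pathways) {
  if (is.data.frame(pathways)) {
    pathways <- split(pathways$gene, pathways$pathway)
  }
  res <- as.data.frame(results)
  out <- list()
  for (pw in names(pathways)) {
    fc <- res$fc[res$gene %in% pathways[[pw]]]
    l2 <- log2(fc[is.finite(fc) & fc > 0])
    if (length(l2) < 2) {
      warning(sprintf("pathway '%s': fewer than 2 members with defined FC; skipped", pw),
              call. = FALSE)
      next
    }
    p <- if (stats::sd(l2) == 0) {
      if (isTRUE(all.equal(mean(l2), 0))) 1 else 0
    } else {
      stats::t.test(l2, mu = 0)$p.value
    }
    out[[length(out) + 1L]] <- data.frame(
      pathway = pw, n_genes = length(l2), mean_log2fc = mean(l2), p = p,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(pathway = character(), n_genes = integer(),
                                      mean_log2fc = numeric(), p = numeric())
  rownames(res) <- NULL
  res
}

#' Cluster-of-differentiation (CD) marker check
#'
#' Per-marker group comparison (fold change, Student t raw p) with no
#' thresholding: a report used to verify that shifts in PBMC subtype
#' composition do not drive the proteome differences. Markers absent from
#' the table are listed as missing.
#'
#' @param table Protein table.
#' @param groups Sample-to-group map.
#' @param cd_genes Marker gene symbols or a path to a one-symbol-per-line
#'   file (default: the packaged 10-marker list).
#' @return Data frame `gene`, `present`, `fc`, `p_raw`.
#' @export
cd_marker_check <- function(table, groups,
                            cd_genes = mecfsomics_extdata("cd_markers.txt")) {
  if (is.character(cd_genes) && length(cd_genes) == 1 &&
      (file.exists(cd_genes) || grepl("[/\\\\]", cd_genes))) {
    cd_genes <- read_gene_list(cd_genes)
  }
  cols <- protein_sample_cols(table, groups)
  pat <- cols[groups$group == "patient"]
  ctl <- cols[groups$group == "control"]
  out <- lapply(cd_genes, function(g) {
    i <- which(table$gene == g)
    if (!length(i)) {
      return(data.frame(gene = g, present = FALSE, fc = NA_real_,
                        p_raw = NA_real_, stringsAsFactors = FALSE))
    }
    x <- as.numeric(table[i[1], pat]); y <- as.numeric(table[i[1], ctl])
    tt <- two_group_t(log2(x), log2(y))
    data.frame(gene = g, present = TRUE, fc = mean(x) / mean(y),
               p_raw = tt$p.value, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a gene list (one symbol per line, '#' comments allowed)
#' @param path File path.
#' @return Character vector of symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop_field("gene list file not found: %s", path)
  x <- readLines(path)
  x <- trimws(sub("#.*$", "", x))
  x[nzchar(x)]
}

## Path to a packaged plain-text fixture.
mecfsomics_extdata <- function(file) {
  system.file("extdata", file, package = "mecfsomics", mustWork = TRUE)
}
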