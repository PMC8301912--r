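## Which injection sits behind each (scheme, section) pair.
injection_of <- function(scheme, section) {
  key <- paste(scheme, section)
  unname(c("A basal" = "basal", "A inj1" = "oligomycin", "A inj2" = "rot_aa",
           "B basal" = "basal", "B inj1" = "fccp",       "B inj2" = "rot_aa",
           "C basal" = "basal", "C inj1" = "oligomycin", "C inj2" = "dg2")[key])
}

#' Section summary policy
#'
#' How the 3 measurement cycles of a section collapse to one per-well value.
#' The default follows vendor report-generator convention: the basal section
#' is averaged, post-inhibitor sections take the extreme reached (minimum
#' after oligomycin, rotenone/antimycin A and 2-DG; maximum after FCCP),
#' which is robust to injection lag.
#'
#' @param basal,oligomycin,fccp,rot_aa,dg2 One of "mean", "min", "max" per
#'   injection.
#' @return A named list of class `summary_policy`.
#' @export
summary_policy <- function(basal = "mean", oligomycin = "min", fccp = "max",
                           rot_aa = "min", dg2 = "min") {
  pol <- list(basal = basal, oligomycin = oligomycin, fccp = fccp,
              rot_aa = rot_aa, dg2 = dg2)
  ok <- vapply(pol, function(p) p %in% c("mean", "min", "max"), logical(1))
  if (!all(ok)) stop_field("summary_policy entries must be 'mean', 'min' or 'max'")
  structure(pol, class = "summary_policy")
}

apply_rule <- function(x, rule) switch(rule, mean = mean(x), min = min(x), max = max(x))

#' Summarise measurement cycles to one value per well and section
#'
#' @param plate A [flux_plate()].
#' @param policy A [summary_policy()].
#' @return Data frame with one row per well: `well`, `scheme`, and columns
#'   `ocr_basal`, `ocr_inj1`, `ocr_inj2`, `ecar_basal`, `ecar_inj1`,
#'   `ecar_inj2`.
#' @export
summarise_sections <- function(plate, policy = summary_policy()) {
  stopifnot(inherits(plate, "flux_plate"))
  tr <- plate$traces
  key <- interaction(tr$well, tr$section, drop = TRUE)
  first <- !duplicated(key)
  out <- tr[first, c("well", "scheme", "section")]
  rule <- policy[injection_of(out$scheme, out$section)]
  out$ocr <- mapply(function(k, r) apply_rule(tr$ocr[key == k], r),
                    as.character(key[first]), rule)
  out$ecar <- mapply(function(k, r) apply_rule(tr$ecar[key == k], r),
                     as.character(key[first]), rule)
  wide <- stats::reshape(out, direction = "wide", idvar = c("well", "scheme"),
                         timevar = "section", v.names = c("ocr", "ecar"),
                         sep = "_")
  rownames(wide) <- NULL
  attr(wide, "policy") <- policy
  wide
}

## Safe ratio: positive denominator required, otherwise flagged undefined (NA).
ratio_or_na <- function(num, den) ifelse(is.finite(den) & den > 0, num / den, NA_real_)

#' Per-well bioenergetic parameters from section summaries
#'
#' Applies the scheme-specific stress-test algebra to each summarised well.
#' Scheme A (oligomycin, rotenone/antimycin A) yields non-mitochondrial
#' respiration, basal mitochondrial respiration (basal minus non-mito),
#' ATP-linked respiration (basal minus post-oligomycin), proton leak
#' (post-oligomycin minus non-mito) and coupling efficiency (100 x ATP-linked
#' / basal mitochondrial). Scheme B (FCCP, rotenone/antimycin A) yields
#' maximal respiration (post-FCCP minus non-mito) and spare respiratory
#' capacity (maximal / basal mitochondrial). Scheme C reads the ECAR channel:
#' non-glycolytic acidification (post-2-DG), glycolysis (basal ECAR minus
#' non-glycolytic), glycolytic capacity (post-oligomycin minus
#' non-glycolytic) and glycolytic reserve (capacity / glycolysis). Ratios
#' with a non-positive denominator are flagged undefined (`NA`), never
#' silently numeric.
#'
#' @param summaries Output of [summarise_sections()].
#' @return Long data frame `well`, `scheme`, `parameter`, `value`. Auxiliary
#'   rows `.basal_ocr` / `.basal_ecar` (schemes A and B) carry the raw basal
#'   signals used later for the subject-level OCR/ECAR ratio.
#' @export
compute_well_parameters <- function(summaries) {
  rows <- list()
  add <- function(well, scheme, parameter, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      well = well, scheme = scheme, parameter = parameter, value = value,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(summaries))) {
    s <- summaries[i, ]
    if (s$scheme == "A") {
      nonmito <- s$ocr_inj2
      basal_resp <- s$ocr_basal - nonmito
      atp <- s$ocr_basal - s$ocr_inj1
      leak <- s$ocr_inj1 - nonmito
      add(s$well, "A", "nonmito_respiration", nonmito)
      add(s$well, "A", "basal_respiration", basal_resp)
      add(s$well, "A", "atp_linked_respiration", atp)
      add(s$well, "A", "proton_leak", leak)
      add(s$well, "A", "coupling_efficiency", 100 * ratio_or_na(atp, basal_resp))
      add(s$well, "A", ".basal_ocr", s$ocr_basal)
      add(s$well, "A", ".basal_ecar", s$ecar_basal)
    } else if (s$scheme == "B") {
      nonmito <- s$ocr_inj2
      basal_resp <- s$ocr_basal - nonmito
      maximal <- s$ocr_inj1 - nonmito
      add(s$well, "B", "nonmito_respiration", nonmito)
      add(s$well, "B", "basal_respiration", basal_resp)
      add(s$well, "B", "maximal_respiration", maximal)
      add(s$well, "B", "spare_respiratory_capacity", ratio_or_na(maximal, basal_resp))
      add(s$well, "B", ".basal_ocr", s$ocr_basal)
      add(s$well, "B", ".basal_ecar", s$ecar_basal)
    } else if (s$scheme == "C") {
      nonglyco <- s$ecar_inj2
      glyco <- s$ecar_basal - nonglyco
      capacity <- s$ecar_inj1 - nonglyco
      add(s$well, "C", "basal_ecar", s$ecar_basal)
      add(s$well, "C", "nonglycolytic_acidification", nonglyco)
      add(s$well, "C", "glycolysis", glyco)
      add(s$well, "C", "glycolytic_capacity", capacity)
      add(s$well, "C", "glycolytic_reserve", ratio_or_na(capacity, glyco))
    }
  }
  do.call(rbind, rows)
}

#' The canonical 14-parameter names, in report order
#' @export
bioenergetic_parameters <- function() {
  c("basal_respiration", "nonmito_respiration", "atp_linked_respiration",
    "proton_leak", "coupling_efficiency", "maximal_respiration",
    "spare_respiratory_capacity", "atp_linked_to_maximal",
    "basal_ecar", "glycolysis", "glycolytic_capacity", "glycolytic_reserve",
    "nonglycolytic_acidification", "ocr_ecar_ratio")
}

#' Aggregate per-well parameters into subject-level bioenergetic profiles
#'
#' Pools each subject's replicate wells per parameter into a mean and sample
#' standard deviation (n - 1; undefined for a single well). The two
#' cross-scheme ratios are computed from subject-level means because the
#' schemes live in different wells and admit no natural pairing: ATP-linked
#' to maximal respiration = mean ATP-linked (scheme A) / mean maximal
#' (scheme B), and the OCR/ECAR ratio = mean basal OCR / mean basal ECAR over
#' the scheme A and B basal sections; their SD is therefore undefined.
#'
#' @param well_params Output of [compute_well_parameters()].
#' @param layout Plate layout (well, subject, group, scheme).
#' @return An object of class `flux_profiles`: a data frame with one row per
#'   subject x parameter (`subject`, `group`, `parameter`, `mean`, `sd`, `n`).
#' @export
aggregate_subjects <- function(well_params, layout) {
  wp <- merge(well_params, layout[, c("well", "subject", "group")], by = "well")
  subjects <- unique(layout[, c("subject", "group")])
  out <- list()
  for (i in seq_len(nrow(subjects))) {
    sb <- subjects$subject[i]
    sub <- wp[wp$subject == sb, ]
    means <- function(p) {
      v <- sub$value[sub$parameter == p]
      v[is.finite(v)]
    }
    for (p in setdiff(bioenergetic_parameters(),
                      c("atp_linked_to_maximal", "ocr_ecar_ratio"))) {
      v <- means(p)
      if (!length(v)) {
        warning(sprintf("subject %s: no wells define parameter '%s'; flagged missing",
                        sb, p), call. = FALSE)
        out[[length(out) + 1L]] <- data.frame(
          subject = sb, group = subjects$group[i], parameter = p,
          mean = NA_real_, sd = NA_real_, n = 0L, stringsAsFactors = FALSE)
      } else {
        out[[length(out) + 1L]] <- data.frame(
          subject = sb, group = subjects$group[i], parameter = p,
          mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else NA_real_,
          n = length(v), stringsAsFactors = FALSE)
      }
    }
    atp <- means("atp_linked_respiration"); mx <- means("maximal_respiration")
    alm <- if (length(atp) && length(mx) && mean(mx) > 0) mean(atp) / mean(mx) else NA_real_
    bo <- means(".basal_ocr"); be <- means(".basal_ecar")
    oer <- if (length(bo) && length(be) && mean(be) > 0) mean(bo) / mean(be) else NA_real_
    out[[length(out) + 1L]] <- data.frame(
      subject = sb, group = subjects$group[i],
      parameter = c("atp_linked_to_maximal", "ocr_ecar_ratio"),
      mean = c(alm, oer), sd = NA_real_,
      n = c(min(length(atp), length(mx)), min(length(bo), length(be))),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$parameter <- factor(res$parameter, levels = bioenergetic_parameters())
  res <- res[order(res$subject, res$parameter), ]
  res$parameter <- as.character(res$parameter)
  rownames(res) <- NULL
  class(res) <- c("flux_profiles", "data.frame")
  res
}

#' Full bioenergetic profiling of a flux plate
#'
#' Convenience wrapper: [summarise_sections()], [compute_well_parameters()]
#' and [aggregate_subjects()] in one call.
#'
#' @param plate A [flux_plate()].
#' @param policy A [summary_policy()].
#' @return A `flux_profiles` object (see [aggregate_subjects()]).
#' @export
bioenergetic_profile <- function(plate, policy = summary_policy()) {
  sums <- summarise_sections(plate, policy)
  wp <- compute_well_parameters(sums)
  aggregate_subjects(wp, plate$layout)
}

#' @export
print.flux_profiles <- function(x, ...) {
  cat(sprintf("Bioenergetic profiles: %d subjects x %d parameters\n",
              length(unique(x$subject)),
              length(unique(x$parameter))))
  print.data.frame(utils::head(as.data.frame(x), 14), digits = 4)
  if (nrow(x) > 14) cat(sprintf("  ... %d more rows\n", nrow(x) - 14))
  invisible(x)
}

#' @export
summary.flux_profiles <- function(object, ...) {
  df <- as.data.frame(object)
  df <- df[!startsWith(df$parameter, "."), ]
  agg <- stats::aggregate(mean ~ parameter + group, data = df, FUN = mean)
  out <- stats::reshape(agg, direction = "wide", idvar = "parameter",
                        timevar = "group", sep = "_")
  rownames(out) <- NULL
  out
}
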