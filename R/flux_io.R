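FLUX_SCHEMES <- c("A", "B", "C")
FLUX_SECTIONS <- c("basal", "inj1", "inj2")

#' Construct and validate a flux plate
#'
#' A flux plate pairs a long-format trace table (one row per well x section x
#' measurement cycle, with simultaneous OCR and ECAR readings) with a plate
#' layout mapping each well to a subject, group and injection scheme. Groups
#' are `patient`, `control` or `calibrator` (inter-experiment reference wells,
#' summarised but excluded from group statistics).
#'
#' @param traces Data frame with columns `well`, `scheme`, `section`, `cycle`,
#'   `ocr`, `ecar` (`subject`/`group` columns are tolerated and ignored in
#'   favour of the layout).
#' @param layout Data frame with columns `well`, `subject`, `group`, `scheme`.
#' @param allow_negative_ocr Permit small negative OCR readings (instrument
#'   noise); by default negative OCR is rejected.
#' @return An object of class `flux_plate`.
#' @export
flux_plate <- function(traces, layout, allow_negative_ocr = FALSE) {
  need_tr <- c("well", "scheme", "section", "cycle", "ocr", "ecar")
  need_ly <- c("well", "subject", "group", "scheme")
  miss <- setdiff(need_tr, names(traces))
  if (length(miss)) stop_field("trace table lacks column(s): %s",
                               paste(miss, collapse = ", "))
  miss <- setdiff(need_ly, names(layout))
  if (length(miss)) stop_field("layout lacks column(s): %s",
                               paste(miss, collapse = ", "))

  bad <- setdiff(unique(traces$scheme), FLUX_SCHEMES)
  if (length(bad)) stop_field("unknown scheme(s): %s", paste(bad, collapse = ", "))
  bad <- setdiff(unique(traces$section), FLUX_SECTIONS)
  if (length(bad)) stop_field("unknown section(s): %s", paste(bad, collapse = ", "))

  only_layout <- setdiff(layout$well, traces$well)
  if (length(only_layout)) {
    stop_field("layout references well(s) with no trace: %s",
               paste(only_layout, collapse = ", "))
  }
  only_traces <- setdiff(traces$well, layout$well)
  if (length(only_traces)) {
    stop_field("trace well(s) missing from layout: %s",
               paste(only_traces, collapse = ", "))
  }
  if (anyDuplicated(layout$well)) {
    stop_field("duplicated well(s) in layout: %s",
               paste(unique(layout$well[duplicated(layout$well)]), collapse = ", "))
  }

  ## every well must carry all three sections with a uniform cycle count
  cnt <- table(traces$well, traces$section)
  if (any(cnt == 0)) {
    i <- which(cnt == 0, arr.ind = TRUE)[1, ]
    stop_field("well %s lacks section '%s'", rownames(cnt)[i[1]], colnames(cnt)[i[2]])
  }
  if (length(unique(as.vector(cnt))) != 1) {
    stop_field("ragged cycle counts: all wells must have the same number of cycles per section")
  }
  if (!allow_negative_ocr && any(traces$ocr < 0, na.rm = TRUE)) {
    stop_field("negative OCR reading(s) present; set allow_negative_ocr = TRUE to keep them")
  }

  traces <- traces[, need_tr]
  layout <- layout[, need_ly]
  structure(list(traces = traces, layout = layout,
                 cycles_per_section = unique(as.vector(cnt))),
            class = "flux_plate")
}

#' Read a flux plate from trace and layout CSV files
#'
#' @param trace_path CSV with columns `well, subject, group, scheme, section,
#'   cycle, ocr, ecar` (subject/group optional).
#' @param layout_path CSV with columns `well, subject, group, scheme`.
#' @param allow_negative_ocr Passed to [flux_plate()].
#' @return A validated `flux_plate`.
#' @export
read_flux_plate <- function(trace_path, layout_path, allow_negative_ocr = FALSE) {
  for (p in c(trace_path, layout_path)) {
    if (!file.exists(p)) stop_field("file not found: %s", p)
  }
  traces <- utils::read.csv(trace_path, stringsAsFactors = FALSE)
  layout <- utils::read.csv(layout_path, stringsAsFactors = FALSE)
  flux_plate(traces, layout, allow_negative_ocr = allow_negative_ocr)
}

#' Write a flux plate to trace and layout CSV files
#'
#' @param plate A `flux_plate`.
#' @param trace_path,layout_path Output CSV paths.
#' @return Invisibly, the paths written.
#' @export
write_flux_plate <- function(plate, trace_path, layout_path) {
  stopifnot(inherits(plate, "flux_plate"))
  tr <- merge(plate$traces, plate$layout[, c("well", "subject", "group")],
              by = "well", sort = FALSE)
  tr <- tr[order(tr$well, tr$section, tr$cycle),
           c("well", "subject", "group", "scheme", "section", "cycle", "ocr", "ecar")]
  utils::write.csv(tr, trace_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(plate$layout, layout_path, row.names = FALSE, quote = FALSE)
  invisible(c(trace_path, layout_path))
}

#' @export
print.flux_plate <- function(x, ...) {
  cat(sprintf("Flux plate: %d wells, %d subjects, %d cycles/section\n",
              nrow(x$layout), length(unique(x$layout$subject)),
              x$cycles_per_section))
  cat("  schemes:", paste(sort(unique(x$layout$scheme)), collapse = " "), "\n")
  invisible(x)
}
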