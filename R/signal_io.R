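# ---- recording container ----------------------------------------------------

#' Construct a two-channel recording
#'
#' Container for one subject's synchronized ECG and PPG: both channels share
#' one uniform time base.
#'
#' @param subject_id Subject identifier.
#' @param fs Sampling rate (Hz), positive.
#' @param ecg ECG samples (mV).
#' @param ppg PPG samples (arbitrary units), same length as \code{ecg}.
#' @param metadata Optional named list (age, sex, ...).
#' @return An object of class \code{"bp_recording"}.
#' @export
recording <- function(subject_id, fs, ecg, ppg, metadata = list()) {
  if (length(ecg) != length(ppg))
    stop("format error: ECG and PPG channels differ in length (",
         length(ecg), " vs ", length(ppg), ")")
  if (!is.numeric(fs) || length(fs) != 1 || is.na(fs) || fs <= 0)
    stop("format error: sampling rate must be a positive number")
  if (anyNA(ecg) || anyNA(ppg))
    stop("format error: missing samples in recording")
  structure(list(subject_id = subject_id, fs = fs,
                 ecg = as.numeric(ecg), ppg = as.numeric(ppg),
                 metadata = metadata),
            class = "bp_recording")
}

#' @export
print.bp_recording <- function(x, ...) {
  cat(sprintf("<bp_recording> subject %s: %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, length(x$ecg), x$fs, length(x$ecg) / x$fs))
  invisible(x)
}

# ---- recording CSV ----------------------------------------------------------

#' Write a recording to CSV
#'
#' Canonical interchange format: comma-separated, '.' decimal, UTF-8, header
#' row \code{time_s,ecg_mv,ppg_au}. Sampling rate and subject id are carried
#' in \code{#}-prefixed comment lines before the header; time is written
#' explicitly even though uniform so the alignment is auditable.
#'
#' @param rec A \code{\link{recording}}.
#' @param path Output file path.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "bp_recording"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# subject_id: %s", rec$subject_id),
               sprintf("# fs_hz: %.10g", rec$fs)), con)
  for (nm in names(rec$metadata))
    writeLines(sprintf("# %s: %s", nm, rec$metadata[[nm]]), con)
  t <- (seq_along(rec$ecg) - 1) / rec$fs
  utils::write.csv(data.frame(time_s = t, ecg_mv = rec$ecg,
                              ppg_au = rec$ppg),
                   con, row.names = FALSE, quote = FALSE)
}

#' Read a recording from CSV
#'
#' @param path CSV file written by \code{\link{write_recording}} (or
#'   following the same dialect).
#' @return A \code{\link{recording}}.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- character(0)
  con <- file(path, open = "r", encoding = "UTF-8")
  repeat {
    ln <- readLines(con, n = 1)
    if (!length(ln) || !startsWith(ln, "#")) break
    hdr <- c(hdr, ln)
  }
  close(con)
  meta <- list()
  for (ln in hdr) {
    kv <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(kv) == 3) meta[[trimws(kv[2])]] <- trimws(kv[3])
  }
  fs <- suppressWarnings(as.numeric(meta[["fs_hz"]]))
  if (is.null(meta[["fs_hz"]]) || is.na(fs))
    stop("format error: unparseable or missing sampling rate (fs_hz)")
  d <- utils::read.csv(path, comment.char = "#")
  need <- c("time_s", "ecg_mv", "ppg_au")
  if (!all(need %in% names(d)))
    stop("format error: expected columns ", paste(need, collapse = ", "))
  n_ecg <- sum(!is.na(d$ecg_mv)); n_ppg <- sum(!is.na(d$ppg_au))
  if (n_ecg != n_ppg)
    stop("format error: ECG and PPG channels differ in length (",
         n_ecg, " vs ", n_ppg, ")")
  extra <- meta[setdiff(names(meta), c("subject_id", "fs_hz"))]
  recording(subject_id = meta[["subject_id"]] %||% basename(path), fs = fs,
            ecg = d$ecg_mv, ppg = d$ppg_au, metadata = extra)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- evaluation report JSON/CSV ---------------------------------------------

report_schema_version <- "1.0"

# recursively replace non-finite leaves with NULL, warning once per field
sanitize_for_json <- function(x, path = "report") {
  if (is.list(x)) {
    for (nm in names(x)) x[[nm]] <- sanitize_for_json(x[[nm]],
                                                      paste(path, nm, sep = "."))
    return(x)
  }
  if (is.numeric(x) && length(x) && any(!is.finite(x) & !is.na(x) |
                                          is.nan(x))) {
    warning("non-finite value in ", path, " serialized as null",
            call. = FALSE)
    x[!is.finite(x)] <- NA_real_
  }
  x
}

#' Write an evaluation report
#'
#' Serializes an agreement/evaluation report to versioned JSON
#' (\code{schema_version} field) and, optionally, its zone table to CSV.
#' Degenerate statistics (NaN p-values from zero-variance subgroups) are
#' written as \code{null} with a warning, never dropped silently.
#'
#' @param report A report list as produced by \code{\link{evaluate_predictions}}.
#' @param path Output JSON path.
#' @param csv_path Optional path for the flat zone/subgroup tables.
#' @export
write_report <- function(report, path, csv_path = NULL) {
  if (is.null(report$n) || report$n < 1)
    stop("refusing to serialize an empty evaluation (0 subjects)")
  report$schema_version <- report$schema_version %||% report_schema_version
  report <- sanitize_for_json(report)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  if (!is.null(csv_path) && !is.null(report$error_grid$sbp)) {
    zt <- do.call(rbind, lapply(c("sbp", "dbp"), function(tg) {
      eg <- report$error_grid[[tg]]
      if (is.null(eg)) return(NULL)
      data.frame(target = tg, zone = names(eg$counts),
                 count = unlist(eg$counts), pct = unlist(eg$percent))
    }))
    utils::write.csv(zt, csv_path, row.names = FALSE)
  }
  invisible(path)
}

#' Read back an evaluation report
#' @param path JSON path written by \code{\link{write_report}}.
#' @return The report list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
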