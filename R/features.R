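# ---- per-beat features ------------------------------------------------------

#' Pulse transit time from R peak to pulse foot
#'
#' @param r_peak_time R-peak time (s).
#' @param b1_time Pulse-foot (B1) time of the same beat (s), strictly after
#'   the R peak.
#' @return PTT in milliseconds.
#' @export
compute_ptt <- function(r_peak_time, b1_time) {
  if (any(b1_time <= r_peak_time))
    stop("ordering error: pulse foot must come after the R peak")
  (b1_time - r_peak_time) * 1000
}

feature_names <- c("ptt_ms", "t_b0_ms", "t_sep_ms", "t_der3_ms",
                   "t_sepmax_ms", "t_srp_ms", "t_dp_ms", "t_end_ms",
                   "log_amp_sep", "log_amp_srp", "log_amp_dp",
                   "aug_index_pct", "perf_index_pct",
                   "bp_0_2", "bp_2_5", "bp_5_10", "spec_centroid_hz",
                   "beat_ms", "upstroke_ms")

#' Compute the feature vector of one beat
#'
#' Regressors for the linear BP model: PTT (R peak to foot, ms), fiducial
#' times relative to the foot (ms), natural-log amplitudes at the ejection,
#' reflected and diastolic peaks (baseline at B1; nonpositive amplitudes are
#' flagged missing, never -Inf), augmentation index (reflected/ejection
#' amplitude ratio, %), perfusion index (pulsatile AC over DC level, %),
#' normalized spectral band powers (0-2, 2-5, 5-10 Hz) with spectral
#' centroid, and the beat's duration and systolic upstroke time.
#'
#' @param fiducials A \code{\link{detect_fiducials}} result.
#' @param beat The corresponding beat.
#' @param fs Sampling rate (Hz).
#' @return Named numeric vector (missing features are \code{NA}).
#' @export
compute_beat_features <- function(fiducials, beat, fs = beat$fs) {
  stopifnot(inherits(fiducials, "fiducial_set"), inherits(beat, "beat_pair"))
  tt <- fiducials$times; aa <- fiducials$amps
  base <- aa[["b1"]]
  rel_ms <- function(p) unname(tt[p] - tt["b1"]) * 1000
  log_amp <- function(p) {
    v <- unname(aa[p]) - base
    if (!is.finite(v) || v <= 0) NA_real_ else log(v)
  }
  a_sep <- aa[["sep"]] - base
  a_srp <- aa[["srp"]] - base
  aug <- if (is.finite(a_sep) && a_sep > 0 && is.finite(a_srp) && a_srp >= 0)
    100 * a_srp / a_sep else NA_real_
  dc <- fiducials$baseline
  ac <- max(beat$ppg) - min(beat$ppg)
  perf <- if (dc > 0) 100 * ac / dc else NA_real_
  sp <- beat_spectrum(beat$ppg, fs)
  c(ptt_ms = compute_ptt(beat$r_time, tt[["b1"]]),
    t_b0_ms = rel_ms("b0"), t_sep_ms = rel_ms("sep"),
    t_der3_ms = rel_ms("der3"), t_sepmax_ms = rel_ms("sepmax"),
    t_srp_ms = rel_ms("srp"),
    t_dp_ms = if (is.na(tt[["dp"]])) NA_real_ else rel_ms("dp"),
    t_end_ms = rel_ms("end"),
    log_amp_sep = log_amp("sep"), log_amp_srp = log_amp("srp"),
    log_amp_dp = if (is.na(aa[["dp"]])) NA_real_ else log_amp("dp"),
    aug_index_pct = aug, perf_index_pct = perf,
    sp,
    beat_ms = length(beat$ppg) / fs * 1000,
    upstroke_ms = rel_ms("sep"))
}

# normalized band powers and spectral centroid of one (baseline-removed) beat
beat_spectrum <- function(y, fs) {
  y <- y - mean(y)
  n <- length(y)
  sp <- Mod(stats::fft(y))^2
  half <- 2:(floor(n / 2) + 1)           # positive frequencies, DC excluded
  f <- (half - 1) * fs / n
  p <- sp[half]
  tot <- sum(p)
  band <- function(lo, hi) if (tot > 0) sum(p[f > lo & f <= hi]) / tot else NA_real_
  c(bp_0_2 = band(0, 2), bp_2_5 = band(2, 5), bp_5_10 = band(5, 10),
    spec_centroid_hz = if (tot > 0) sum(f * p) / tot else NA_real_)
}

# ---- record-level aggregation -----------------------------------------------

#' Aggregate per-beat features over a record
#'
#' Per-feature median across accepted beats (median, not mean, so residual
#' artifact beats cannot drag the record-level value); beats missing a
#' feature are excluded feature-wise, never imputed.
#'
#' @param per_beat data.frame of per-beat feature vectors (one row per
#'   accepted beat).
#' @param min_beats Minimum accepted beats required (default 10).
#' @return One-row data.frame of medians with an \code{n_beats} column.
#' @export
aggregate_record <- function(per_beat, min_beats = 10) {
  if (is.null(per_beat) || nrow(per_beat) < min_beats)
    stop("record-rejected error: fewer than ", min_beats, " accepted beats (",
         if (is.null(per_beat)) 0 else nrow(per_beat), ")")
  med <- vapply(per_beat, function(col) {
    v <- stats::median(col, na.rm = TRUE)
    if (is.nan(v)) NA_real_ else v
  }, numeric(1))
  out <- as.data.frame(as.list(med))
  out$n_beats <- nrow(per_beat)
  out
}

#' Extract the record-level feature vector from one recording
#'
#' Full per-record path: R-peak detection, R-to-R segmentation, quality
#' gating, per-beat fiducial detection (beats whose fiducials cannot be
#' resolved are demoted to rejected), per-beat features, then median
#' aggregation.
#'
#' @param rec A \code{\link{recording}}.
#' @param quality_threshold Quality-gate threshold (default 0.9).
#' @param min_beats Minimum accepted beats (default 10).
#' @return List with \code{features} (one-row data.frame), \code{beats}
#'   (gated beats), \code{fiducials} (per accepted beat), \code{r_peaks}.
#' @export
extract_features <- function(rec, quality_threshold = 0.9, min_beats = 10) {
  r_peaks <- detect_r_peaks(rec)
  beats <- segment_beats(rec, r_peaks)
  beats <- quality_gate(beats, quality_threshold)
  rows <- list(); fids <- list()
  for (b in beats) {
    if (!isTRUE(b$accepted)) next
    fid <- tryCatch(detect_fiducials(b), error = function(e) NULL)
    if (is.null(fid)) next
    fv <- tryCatch(compute_beat_features(fid, b), error = function(e) NULL)
    if (is.null(fv)) next
    rows[[length(rows) + 1]] <- as.data.frame(as.list(fv))
    fids[[length(fids) + 1]] <- fid
  }
  per_beat <- if (length(rows)) do.call(rbind, rows) else NULL
  feats <- aggregate_record(per_beat, min_beats)
  feats$subject <- rec$subject_id
  list(features = feats, beats = beats, fiducials = fids, r_peaks = r_peaks)
}
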