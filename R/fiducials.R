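# ---- R-peak detection -------------------------------------------------------

#' Detect ECG R peaks
#'
#' Energy-based QRS detector in the Pan-Tompkins spirit: derivative,
#' squaring, moving-window integration (120 ms), adaptive threshold on the
#' integrated energy, then peak refinement on the raw signal with a 250 ms
#' refractory period.
#'
#' @param rec A \code{\link{recording}} (fs >= 100 Hz).
#' @param refractory_s Minimum separation between successive peaks (s).
#' @return Strictly increasing R-peak times (s).
#' @export
detect_r_peaks <- function(rec, refractory_s = 0.25) {
  stopifnot(inherits(rec, "bp_recording"))
  if (rec$fs < 100) stop("sampling rate below 100 Hz")
  x <- rec$ecg
  if (anyNA(x) || stats::sd(x) < .Machine$double.eps^0.5)
    stop("no-signal error: ECG channel is flat or contains missing samples")
  fs <- rec$fs
  # zero-phase 5-25 Hz bandpass isolates QRS energy before differentiation
  # (differentiating raw wideband noise swamps the QRS at high fs)
  bp <- signal::filtfilt(signal::butter(2, c(5, 25) / (fs / 2), "pass"), x)
  d <- c(0, diff(bp)) * fs
  w <- max(3, round(0.12 * fs))
  env <- as.numeric(stats::filter(d^2, rep(1, w) / w, sides = 2))
  env[is.na(env)] <- 0
  # threshold between the noise floor (median) and the QRS level (top 0.5%)
  floor_ <- stats::median(env)
  top <- stats::quantile(env, 0.995)
  if (top <= 0 || top <= floor_ * 1.5)
    stop("no-signal error: ECG energy envelope is degenerate")
  thr <- floor_ + 0.35 * (top - floor_)
  above <- env > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  regions <- cbind(starts[r$values], ends[r$values])
  if (!nrow(regions)) stop("no-signal error: no QRS-like activity found")
  pad <- round(0.03 * fs)
  peaks <- apply(regions, 1, function(rg) {
    i0 <- max(1, rg[1] - pad); i1 <- min(length(x), rg[2] + pad)
    i0 + which.max(bp[i0:i1]) - 1
  })
  # refractory: keep the larger of any pair closer than refractory_s
  peaks <- sort(unique(peaks))
  keep <- logical(length(peaks))
  last <- -Inf
  for (i in seq_along(peaks)) {
    if ((peaks[i] - last) / fs >= refractory_s) {
      keep[i] <- TRUE; last <- peaks[i]
    } else if (bp[peaks[i]] > bp[which(keep)[sum(keep)]]) {
      keep[which(keep)[sum(keep)]] <- FALSE
      keep[i] <- TRUE; last <- peaks[i]
    }
  }
  (peaks[keep] - 1) / fs
}

# ---- beat segmentation ------------------------------------------------------

#' Segment a recording into cardiac cycles
#'
#' Each beat's PPG segment spans from one R peak to the sample before the
#' next R peak, so segments tile the inter-peak span of the record with no
#' gaps or overlaps; the partial cycles before the first and after the last
#' R peak are dropped.
#'
#' @param rec A \code{\link{recording}}.
#' @param r_peaks R-peak times (s) from \code{\link{detect_r_peaks}}.
#' @return List of beats, each a list with \code{r_time} (s), \code{fs},
#'   \code{ppg} (segment samples), \code{i_start} (1-based index into the
#'   record), \code{quality} and \code{accepted} (filled by
#'   \code{\link{quality_gate}}).
#' @export
segment_beats <- function(rec, r_peaks) {
  stopifnot(inherits(rec, "bp_recording"))
  if (length(r_peaks) < 2)
    stop("insufficient-data error: need at least 2 R peaks")
  idx <- round(r_peaks * rec$fs) + 1
  beats <- vector("list", length(idx) - 1)
  for (b in seq_len(length(idx) - 1)) {
    beats[[b]] <- structure(
      list(beat = b, r_time = (idx[b] - 1) / rec$fs, fs = rec$fs,
           ppg = rec$ppg[idx[b]:(idx[b + 1] - 1)], i_start = idx[b],
           quality = NA_real_, accepted = NA),
      class = "beat_pair")
  }
  beats
}

# ---- quality gate -----------------------------------------------------------

#' Score beats against the record's template and gate on quality
#'
#' Each beat's PPG, linearly resampled to a fixed length of 200 samples, is
#' correlated against the record's median template (columnwise median of all
#' resampled beats). The quality score is the correlation clamped to
#' [0, 1]; a beat is accepted iff its score reaches \code{threshold}.
#' Mirrors the automatic per-cardiocycle quality comparison used by
#' ambulatory devices: corrupted cycles are excluded before analysis.
#'
#' @param beats List of beats from \code{\link{segment_beats}}.
#' @param threshold Acceptance threshold in [0, 1] (default 0.9).
#' @return The beats with \code{quality} and \code{accepted} filled.
#' @export
quality_gate <- function(beats, threshold = 0.9) {
  if (length(beats) < 3) stop("need at least 3 beats for a quality template")
  L <- 200
  res <- vapply(beats, function(b)
    stats::approx(seq_along(b$ppg), b$ppg, n = L)$y, numeric(L))
  template <- apply(res, 1, stats::median)
  tsd <- stats::sd(template)
  for (i in seq_along(beats)) {
    bsd <- stats::sd(res[, i])
    r <- if (tsd > 0 && bsd > 0) stats::cor(res[, i], template) else 0
    beats[[i]]$quality <- min(1, max(0, r))
    beats[[i]]$accepted <- beats[[i]]$quality >= threshold
  }
  if (!any(vapply(beats, `[[`, logical(1), "accepted")))
    stop("record-rejected error: no beat passed the quality gate")
  beats
}

# ---- fiducial detection -----------------------------------------------------

sg_smooth <- function(x, fs, m = 0, width_s = 0.021, p = 3) {
  n <- max(p + 2, round(width_s * fs))
  if (n %% 2 == 0) n <- n + 1
  if (n >= length(x)) n <- (length(x) - 2) %/% 2 * 2 + 1
  signal::sgolayfilt(x, p = max(p, m), n = n, m = m, ts = 1 / fs)
}

# first index in (from, to) that is the maximum of its +/- halfwin
# neighbourhood, strictly above the window edges, and at least min_height;
# halfwin > 1 makes the search ignore noise ripple
first_local_max <- function(x, from, to, min_height = -Inf, halfwin = 1L) {
  from <- max(from, halfwin + 1L); to <- min(to, length(x) - halfwin)
  if (to < from) return(NA_integer_)
  for (i in from:to) {
    if (x[i] >= min_height &&
        x[i] >= max(x[(i - halfwin):(i + halfwin)]) &&
        x[i] > x[i - halfwin] && x[i] > x[i + halfwin])
      return(i)
  }
  NA_integer_
}

#' Detect the eight pulse-wave fiducial points of one beat
#'
#' Landmarks on the PPG pulse: B1 (foot, by the intersecting-tangent
#' method), B0 (maximum upstroke slope), SEP (systolic ejection peak), DER3
#' (first positive peak of the third derivative after B1), SEPMAX (first
#' zero-crossing of the second derivative after SEP), SRP (reflected
#' systolic peak: first local maximum after SEP, or the most concave
#' shoulder when the reflected wave does not form its own maximum), DP
#' (diastolic peak after the dicrotic region, absent in pulses without a
#' diastolic wave), and End (end of the wave, the last sample of the
#' cycle). Derivatives are taken on a Savitzky-Golay smoothed beat
#' (polynomial order 3, ~21 ms window) because third derivatives amplify
#' noise.
#'
#' @param beat A beat from \code{\link{segment_beats}} (accepted).
#' @param fs Sampling rate (Hz); defaults to the beat's.
#' @param sg_width_s Smoothing window (s).
#' @return An object of class \code{"fiducial_set"}: list with \code{times}
#'   (absolute s) and \code{amps} (PPG units) for b1, b0, sep, der3,
#'   sepmax, srp, dp, end (\code{dp} may be \code{NA}).
#' @export
detect_fiducials <- function(beat, fs = beat$fs, sg_width_s = 0.021) {
  stopifnot(inherits(beat, "beat_pair"))
  if (isFALSE(beat$accepted))
    stop("fiducial-failure error: beat was rejected by the quality gate")
  y <- beat$ppg
  n <- length(y)
  if (n < round(0.05 * fs)) stop("fiducial-failure error: segment too short")
  ps <- sg_smooth(y, fs, 0, sg_width_s)
  d1 <- sg_smooth(y, fs, 1, sg_width_s)
  d2 <- sg_smooth(y, fs, 2, sg_width_s)
  d3 <- sg_smooth(y, fs, 3, max(sg_width_s, 0.031), p = 5)
  imax <- which.max(ps)
  base <- min(ps[1:imax])
  amp <- ps[imax] - base
  if (amp <= 0 || max(d1[1:imax]) <= 0)
    stop("fiducial-failure error: no detectable upstroke")
  wpk <- max(2L, round(0.02 * fs))
  # SEP: first local maximum with at least 60% of the pulse amplitude
  sep_i <- first_local_max(ps, 2, n - 1, base + 0.6 * amp, halfwin = wpk)
  if (is.na(sep_i)) sep_i <- imax
  # B0: maximum of the first derivative on the rising edge
  b0_i <- which.max(d1[1:sep_i])
  # refine B0 by quadratic interpolation of the derivative peak
  b0_off <- 0
  if (b0_i > 1 && b0_i < sep_i) {
    den <- d1[b0_i - 1] - 2 * d1[b0_i] + d1[b0_i + 1]
    if (den < 0) b0_off <- 0.5 * (d1[b0_i - 1] - d1[b0_i + 1]) / den
  }
  b0_t <- (b0_i - 1 + b0_off) / fs
  d1_b0 <- d1[b0_i]
  ps_b0 <- ps[b0_i] + b0_off * d1[b0_i] / fs
  # B1: intersecting tangents - tangent at B0 meets the pre-upstroke baseline
  b1_t <- b0_t - (ps_b0 - base) / d1_b0
  if (!is.finite(b1_t) || b1_t < 0 || b1_t >= b0_t)
    stop("fiducial-failure error: tangent foot outside the rising edge")
  b1_i <- max(1, min(n, round(b1_t * fs) + 1))
  # DER3: first positive peak of the third derivative after B1
  der3_i <- first_local_max(d3, max(b1_i, 2), sep_i + round(0.1 * fs), 0,
                            halfwin = 2L)
  if (is.na(der3_i)) der3_i <- b1_i + 1
  # SEPMAX: first zero-crossing of the second derivative after SEP
  sepmax_i <- NA_integer_
  for (i in (sep_i + 1):(n - 1)) {
    if (!is.na(d2[i]) && d2[i] <= 0 && d2[i + 1] > 0) { sepmax_i <- i; break }
  }
  if (is.na(sepmax_i)) sepmax_i <- min(sep_i + 2, n - 1)
  # SRP and DP from the local maxima after SEP
  min_sep_gap <- round(0.04 * fs)
  maxima <- integer(0)
  i <- sep_i + min_sep_gap
  while (!is.na(i) && i < n - 1) {
    m <- first_local_max(ps, i, n - 1, base + 0.08 * amp, halfwin = wpk)
    if (is.na(m)) break
    maxima <- c(maxima, m)
    i <- m + min_sep_gap
  }
  srp_i <- NA_integer_; dp_i <- NA_integer_
  if (length(maxima) >= 2) {
    srp_i <- maxima[1]; dp_i <- maxima[2]
  } else if (length(maxima) == 1) {
    # a lone maximum: decide whether the reflected wave is a shoulder before
    # it (then the maximum is the diastolic peak) or the maximum itself
    sh <- shoulder_index(d2, sepmax_i, maxima[1] - min_sep_gap, fs)
    if (!is.na(sh) && (maxima[1] - sh) > min_sep_gap) {
      srp_i <- sh; dp_i <- maxima[1]
    } else {
      srp_i <- maxima[1]
    }
  } else {
    sh <- shoulder_index(d2, sepmax_i, n - 1, fs)
    srp_i <- if (!is.na(sh)) sh else sep_i
  }
  t0 <- beat$r_time
  times <- c(b1 = t0 + b1_t, b0 = t0 + b0_t,
             sep = t0 + (sep_i - 1) / fs, der3 = t0 + (der3_i - 1) / fs,
             sepmax = t0 + (sepmax_i - 1) / fs,
             srp = t0 + (srp_i - 1) / fs,
             dp = if (is.na(dp_i)) NA_real_ else t0 + (dp_i - 1) / fs,
             end = t0 + (n - 1) / fs)
  amps <- c(b1 = ps[b1_i], b0 = ps[b0_i], sep = ps[sep_i], der3 = ps[der3_i],
            sepmax = ps[sepmax_i], srp = ps[srp_i],
            dp = if (is.na(dp_i)) NA_real_ else ps[dp_i], end = ps[n])
  fid <- structure(list(times = times, amps = amps, baseline = base),
                   class = "fiducial_set")
  validate_fiducials(fid)
  fid
}

# most concave point (local max of -d2) in (from, to)
shoulder_index <- function(d2, from, to, fs = 1000) {
  if (is.na(from) || is.na(to) || to - from < 3) return(NA_integer_)
  first_local_max(-d2, from, to, halfwin = max(2L, round(0.015 * fs)))
}

validate_fiducials <- function(fid) {
  tt <- fid$times
  ok <- tt["b1"] < tt["b0"] && tt["b0"] < tt["sep"] &&
    tt["sep"] < tt["end"] && tt["srp"] >= tt["sep"] &&
    (is.na(tt["dp"]) || tt["dp"] > tt["srp"]) &&
    tt["der3"] > tt["b1"] && tt["der3"] < tt["end"] &&
    tt["sepmax"] > tt["b1"] && tt["sepmax"] < tt["end"]
  if (!isTRUE(ok))
    stop("fiducial-failure error: fiducial ordering invariant violated")
  invisible(fid)
}

# ---- forward/backward wave decomposition ------------------------------------

#' Decompose a pulse wave into forward and backward components
#'
#' Nonlinear least-squares fit (Levenberg-Marquardt) of two positive
#' Gaussian components plus a constant baseline to the beat's PPG: the
#' forward (ejection) wave and the backward (reflected) wave returning from
#' the periphery. The forward component is constrained to peak before the
#' backward one (components are sorted if the fit crosses them). A fit whose
#' residual energy exceeds \code{max_residual_frac} of the baseline-corrected
#' signal energy, or that fails to converge, is flagged unreliable rather
#' than raising an error.
#'
#' @param beat A beat from \code{\link{segment_beats}}.
#' @param fiducials Optional \code{\link{detect_fiducials}} result used for
#'   starting values.
#' @param max_residual_frac Reliability threshold on residual energy
#'   fraction (default 0.1).
#' @return List with \code{forward} and \code{backward} (each
#'   \code{c(amplitude, center_s, width_s)}; centers in absolute time),
#'   \code{baseline}, \code{residual_norm}, \code{residual_frac},
#'   \code{reliable}.
#' @export
decompose_waves <- function(beat, fiducials = NULL, max_residual_frac = 0.1) {
  stopifnot(inherits(beat, "beat_pair"))
  y <- beat$ppg; fs <- beat$fs
  t <- (seq_along(y) - 1) / fs
  if (is.null(fiducials))
    fiducials <- detect_fiducials(beat)
  tt <- fiducials$times - beat$r_time
  base0 <- fiducials$baseline
  a1 <- max(fiducials$amps["sep"] - base0, 1e-3)
  a2 <- max(if (is.na(fiducials$amps["srp"])) 0.4 * a1
            else fiducials$amps["srp"] - base0, 1e-3)
  st <- list(b = base0, a1 = a1, c1 = tt[["sep"]],
             w1 = max((tt[["sep"]] - tt[["b1"]]) * 0.45, 0.01),
             a2 = min(a2, 0.95 * a1), c2 = max(tt[["srp"]], tt[["sep"]] + 0.05),
             w2 = 0.07)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ b + a1 * exp(-(t - c1)^2 / (2 * w1^2)) +
        a2 * exp(-(t - c2)^2 / (2 * w2^2)),
      start = st,
      lower = c(b = -Inf, a1 = 0, c1 = 0, w1 = 0.005, a2 = 0, c2 = 0,
                w2 = 0.005),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(forward = NULL, backward = NULL, baseline = NA_real_,
                residual_norm = NA_real_, residual_frac = NA_real_,
                reliable = FALSE))
  }
  p <- as.list(stats::coef(fit))
  comps <- list(c(amplitude = p$a1, center_s = p$c1, width_s = p$w1),
                c(amplitude = p$a2, center_s = p$c2, width_s = p$w2))
  ord <- order(vapply(comps, `[[`, numeric(1), "center_s"))
  comps <- comps[ord]
  res <- stats::resid(fit)
  energy <- sum((y - p$b)^2)
  frac <- if (energy > 0) sum(res^2) / energy else NA_real_
  for (k in 1:2) comps[[k]]["center_s"] <- comps[[k]]["center_s"] + beat$r_time
  list(forward = comps[[1]], backward = comps[[2]], baseline = p$b,
       residual_norm = sqrt(sum(res^2)),
       residual_frac = frac,
       reliable = is.finite(frac) && frac <= max_residual_frac)
}
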