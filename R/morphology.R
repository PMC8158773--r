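#' Pulse-wave morphology parameters
#'
#' Defines one cardiac cycle's PPG pulse as a sum of three positive Gaussian
#' components on a DC baseline: the systolic ejection wave, the reflected
#' systolic wave returning from the periphery, and the diastolic wave.  The
#' three-component form keeps every labelled landmark of the wave (foot,
#' maximum upstroke, ejection peak, reflected peak, diastolic peak)
#' analytically accessible, which is what makes the generator usable as a
#' ground-truth oracle for the fiducial detector.
#'
#' Component centers are expressed in beat-local time (seconds from an
#' arbitrary origin); the synthesizer later shifts the whole wave so that its
#' intersecting-tangent foot lands exactly at R-peak time + \code{ptt}.
#'
#' @param a_sep,a_srp,a_dp Component amplitudes (arbitrary PPG units).
#'   \code{a_sep > 0}; \code{a_srp < a_sep}; \code{a_srp}, \code{a_dp} may be
#'   zero (degenerate single-component pulses used in tests).
#' @param c_sep,c_srp,c_dp Component centers (s, beat-local), strictly
#'   increasing.
#' @param w_sep,w_srp,w_dp Component Gaussian widths (s), all positive.
#' @param baseline DC level of the PPG channel (arbitrary units).
#' @param ptt True pulse transit time: delay from the ECG R peak to the pulse
#'   foot (s). Must satisfy \code{0 < ptt < period}.
#' @param period Beat period (s).
#' @return An object of class \code{"morph_params"}.
#' @export
morphology_params <- function(a_sep = 1.0, a_srp = 0.45, a_dp = 0.25,
                              c_sep = 0.14, c_srp = 0.34, c_dp = 0.52,
                              w_sep = 0.040, w_srp = 0.075, w_dp = 0.060,
                              baseline = 20, ptt = 0.20, period = 1.0) {
  m <- list(a = c(sep = a_sep, srp = a_srp, dp = a_dp),
            centers = c(sep = c_sep, srp = c_srp, dp = c_dp),
            widths = c(sep = w_sep, srp = w_srp, dp = w_dp),
            baseline = baseline, ptt = ptt, period = period)
  class(m) <- "morph_params"
  validate_morphology(m)
  m
}

validate_morphology <- function(m) {
  stopifnot(inherits(m, "morph_params"))
  if (m$a["sep"] <= 0 || any(m$a < 0))
    stop("component amplitudes must be positive (a_srp/a_dp may be zero)")
  if (m$a["srp"] >= m$a["sep"])
    stop("reflected-wave amplitude must be smaller than ejection amplitude")
  if (any(diff(m$centers) <= 0))
    stop("component centers must be strictly increasing")
  if (any(m$widths <= 0)) stop("component widths must be positive")
  if (m$ptt <= 0 || m$ptt >= m$period)
    stop("ptt must lie strictly inside (0, period)")
  # last component center, placed in absolute beat time (foot at R + ptt,
  # foot approximated as c_sep - 2*w_sep), must fall inside the beat
  foot_local <- m$centers["sep"] - 2 * m$widths["sep"]
  if (m$ptt + (m$centers["dp"] - foot_local) >= m$period)
    stop("component centers exceed the beat period")
  invisible(m)
}

# Continuous noise-free pulse (baseline-corrected) and its first derivative,
# in beat-local time. Vectorized over t.
pulse_value <- function(m, t) {
  v <- 0
  for (k in 1:3)
    v <- v + m$a[[k]] * exp(-(t - m$centers[[k]])^2 / (2 * m$widths[[k]]^2))
  v
}

pulse_deriv <- function(m, t) {
  v <- 0
  for (k in 1:3) {
    z <- (t - m$centers[[k]]) / m$widths[[k]]
    v <- v - m$a[[k]] * z / m$widths[[k]] * exp(-z^2 / 2)
  }
  v
}

#' Ground-truth fiducial points of a continuous pulse model
#'
#' Locates the landmark points of the noise-free continuous waveform by
#' numerical optimization of the analytic model: the maximum-upstroke point
#' (B0) as the maximum of the first derivative on the rising edge, the foot
#' (B1) by the intersecting-tangent construction (tangent at B0 intersected
#' with the pre-upstroke baseline), and the ejection (SEP), reflected (SRP)
#' and diastolic (DP) peaks as local maxima of the full mixture bracketed
#' around their component centers.  Times are beat-local seconds; amplitudes
#' are baseline-corrected PPG units.
#'
#' @param m A \code{\link{morphology_params}} object.
#' @return A list with elements \code{b1}, \code{b0}, \code{sep}, \code{srp},
#'   \code{dp} (each \code{c(t = , a = )}; \code{dp} is \code{NULL} when the
#'   diastolic component is absent or leaves no local maximum).
#' @export
true_fiducials <- function(m) {
  cs <- m$centers; ws <- m$widths
  # B0: max of derivative on the rising edge of the ejection wave
  ob0 <- stats::optimize(function(t) pulse_deriv(m, t),
                         lower = cs[1] - 4 * ws[1], upper = cs[1],
                         maximum = TRUE, tol = 1e-9)
  b0 <- ob0$maximum
  # B1: intersecting tangents (tangent at B0 vs zero baseline)
  b1 <- b0 - pulse_value(m, b0) / pulse_deriv(m, b0)
  # SEP: local max near ejection center
  osep <- stats::optimize(function(t) pulse_value(m, t),
                          lower = b0, upper = (cs[1] + cs[2]) / 2,
                          maximum = TRUE, tol = 1e-9)
  out <- list(
    b1 = c(t = unname(b1), a = pulse_value(m, b1)),
    b0 = c(t = unname(b0), a = pulse_value(m, b0)),
    sep = c(t = unname(osep$maximum), a = unname(osep$objective)))
  # SRP / DP: local maxima after the ejection peak are the downward
  # zero-crossings of the analytic derivative; each is attributed to the
  # nearest component center. A reflected or diastolic component whose bump
  # is swallowed by its neighbour's flank leaves no crossing: that landmark
  # is genuinely absent from the wave, not forced.
  t_hi <- cs[3] + 3 * ws[3]
  tg <- seq(out$sep["t"] + 2e-3, t_hi, by = 5e-4)
  dv <- pulse_deriv(m, tg)
  cross <- which(dv[-length(dv)] > 0 & dv[-1] <= 0)
  for (i in cross) {
    root <- stats::uniroot(function(t) pulse_deriv(m, t),
                           c(tg[i], tg[i + 1]), tol = 1e-10)$root
    nm <- c("srp", "dp")[which.min(abs(root - cs[2:3]))]
    if (m$a[[nm]] > 0 && is.null(out[[nm]]))
      out[[nm]] <- c(t = root, a = pulse_value(m, root))
  }
  out
}
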