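# ---- truncated-normal helpers -----------------------------------------------

# mean and sd of N(mu, sigma) truncated to [lo, hi]
trunc_norm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
  Z <- stats::pnorm(b) - stats::pnorm(a)
  pa <- stats::dnorm(a); pb <- stats::dnorm(b)
  m <- mu + sigma * (pa - pb) / Z
  v <- sigma^2 * (1 + (a * pa - b * pb) / Z - ((pa - pb) / Z)^2)
  c(mean = m, sd = sqrt(v))
}

# parent (mu, sigma) such that the truncated distribution has the target
# mean/sd; truncation is asymmetric here (the lower bound sits closer to the
# mean than the upper), so using the targets as parent parameters would bias
# the realized cohort mean upward by about a tenth of an sd
match_trunc_norm <- function(target_mean, target_sd, lo, hi) {
  if (abs(target_mean - (lo + hi) / 2) > 5 * target_sd ||
      target_mean < lo || target_mean > hi)
    stop("infeasible truncation: target mean too far outside the bounds")
  obj <- function(p) {
    mm <- trunc_norm_moments(p[1], exp(p[2]), lo, hi)
    (mm["mean"] - target_mean)^2 + (mm["sd"] - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

rtrunc_norm <- function(n, mu, sigma, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 10, mu, sigma)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# ---- cohort parameters ------------------------------------------------------

#' Synthetic cohort parameters
#'
#' Study conditions for the synthetic cohort: blood-pressure distributions
#' matching the reported patient population (SBP mean 125, sd 18.8, range
#' 90--175 mmHg; DBP mean 76, sd 12.4, range 54--105 mmHg), an affine
#' decreasing coupling from SBP to pulse transit time, an affine decreasing
#' coupling from DBP to the reflected-wave delay, heart-rate distribution,
#' and the noise levels of the signal channels and of the cuff reference.
#'
#' The stated BP mean/sd are the moments of the *truncated* distribution:
#' parent normal parameters are solved internally by moment matching.
#'
#' @param n Number of subjects.
#' @param sbp_mean,sbp_sd,sbp_range Systolic BP distribution (mmHg).
#' @param dbp_mean,dbp_sd,dbp_range Diastolic BP distribution (mmHg).
#' @param bp_cor Latent correlation between SBP and DBP.
#' @param min_pulse_pressure Pairs with SBP - DBP below this are redrawn.
#' @param hr_mean,hr_sd,hr_range Heart rate distribution (bpm).
#' @param ptt_intercept,ptt_slope PTT coupling: true PTT (ms) =
#'   intercept + slope * SBP + jitter. Slope is negative: higher pressure,
#'   stiffer vessels, faster wave arrival.
#' @param ptt_jitter_sd Subject-level PTT jitter sd (ms) around the coupling
#'   line.
#' @param srp_delay_intercept,srp_delay_slope Reflected-wave delay coupling:
#'   delay (s) from ejection to reflected component center =
#'   intercept + slope * DBP.
#' @param srp_jitter_sd Subject-level reflected-delay jitter sd (s).
#' @param noise_sd_ppg,noise_sd_ecg Additive white noise sd on the PPG
#'   (PPG units) and ECG (mV) channels.
#' @param cuff_sd Per-reading cuff noise sd (mmHg); each subject gets three
#'   independent readings whose mean is the reference.
#' @param duration_s,fs Record duration (s) and sampling rate (Hz).
#' @param seed Integer seed; the whole cohort (BP draws, morphologies,
#'   signal noise, cuff readings) is drawn from the single RNG stream this
#'   seed initializes, in subject order.
#' @return An object of class \code{"cohort_params"}.
#' @export
cohort_params <- function(n = 200,
                          sbp_mean = 125, sbp_sd = 18.8,
                          sbp_range = c(90, 175),
                          dbp_mean = 76, dbp_sd = 12.4,
                          dbp_range = c(54, 105),
                          bp_cor = 0.6, min_pulse_pressure = 15,
                          hr_mean = 64, hr_sd = 6, hr_range = c(50, 78),
                          ptt_intercept = 400, ptt_slope = -1.5,
                          ptt_jitter_sd = 4,
                          srp_delay_intercept = 0.27,
                          srp_delay_slope = -0.0010,
                          srp_jitter_sd = 0.003,
                          noise_sd_ppg = 0.02, noise_sd_ecg = 0.02,
                          cuff_sd = 3,
                          duration_s = 180, fs = 1000, seed = 1L) {
  stopifnot(n >= 1, fs > 0, duration_s > 0, cuff_sd >= 0,
            ptt_slope < 0, srp_delay_slope < 0)
  p <- as.list(environment())
  p$sbp_parent <- match_trunc_norm(sbp_mean, sbp_sd, sbp_range[1], sbp_range[2])
  p$dbp_parent <- match_trunc_norm(dbp_mean, dbp_sd, dbp_range[1], dbp_range[2])
  class(p) <- "cohort_params"
  p
}

# inverse of the BP -> waveform coupling, used by noise-free invertibility
# checks: recover SBP from a PTT in ms, DBP from a reflected delay in s
inverse_coupling_sbp <- function(ptt_ms, params)
  (ptt_ms - params$ptt_intercept) / params$ptt_slope

inverse_coupling_dbp <- function(srp_delay_s, params)
  (srp_delay_s - params$srp_delay_intercept) / params$srp_delay_slope

# ---- beat and recording synthesis -------------------------------------------

# ECG template: R-dominant narrow Gaussian, amplitude 1 mV, width 8 ms.
# Only R timing feeds the method, so full PQRST morphology is not modelled.
ecg_r_width <- 0.008

add_gaussians <- function(y, t, centers, amps, widths) {
  for (k in seq_along(centers)) {
    lo <- centers[k] - 5 * widths[k]; hi <- centers[k] + 5 * widths[k]
    i <- which(t >= lo & t <= hi)
    if (length(i))
      y[i] <- y[i] + amps[k] * exp(-(t[i] - centers[k])^2 / (2 * widths[k]^2))
  }
  y
}

#' Synthesize a single cardiac cycle (ECG + PPG) with ground truth
#'
#' Builds one beat at sampling rate \code{fs}: an R-dominant ECG deflection
#' and a PPG pulse that is the sum of the morphology's three Gaussian
#' components on the DC baseline. The waveform is placed so that its
#' intersecting-tangent foot falls exactly at R-peak time + \code{morph$ptt};
#' the returned ground truth holds the exact continuous-model fiducial times
#' and amplitudes.
#'
#' @param morph A \code{\link{morphology_params}} object.
#' @param fs Sampling rate (Hz), at least 100.
#' @param noise_sd Additive white-noise sd on the PPG channel (PPG units).
#' @param seed Optional integer seed (only needed when calling stand-alone;
#'   inside \code{\link{generate_cohort}} the cohort stream is used).
#' @param r_time R-peak time within the synthesized window (s).
#' @return List with \code{time}, \code{ecg}, \code{ppg} vectors and a
#'   \code{truth} list (absolute-time fiducials \code{b1}, \code{b0},
#'   \code{sep}, \code{srp}, \code{dp}, plus \code{r_time}, \code{ptt_ms}).
#' @export
synthesize_beat <- function(morph, fs = 1000, noise_sd = 0, seed = NULL,
                            r_time = 0.1) {
  validate_morphology(morph)
  stopifnot(fs >= 100)
  if (!is.null(seed)) set.seed(seed)
  dur <- r_time + morph$period
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  ecg <- add_gaussians(numeric(length(t)), t, r_time, 1, ecg_r_width)
  tf <- true_fiducials(morph)
  shift <- r_time + morph$ptt - unname(tf$b1["t"])  # foot lands at R + ptt
  ppg <- add_gaussians(rep(morph$baseline, length(t)), t,
                       morph$centers + shift, morph$a, morph$widths)
  if (noise_sd > 0) ppg <- ppg + stats::rnorm(length(t), 0, noise_sd)
  truth <- lapply(tf, function(p)
    if (is.null(p)) NULL else c(t = unname(p["t"]) + shift, a = unname(p["a"])))
  truth$r_time <- r_time
  truth$ptt_ms <- morph$ptt * 1000
  list(time = t, ecg = ecg, ppg = ppg, truth = truth)
}

#' Synthesize a full two-channel recording with per-beat ground truth
#'
#' Tiles one subject's beats at the RR interval given by \code{hr_bpm}
#' (optionally with beat-to-beat timing jitter), placing each pulse so its
#' intersecting-tangent foot falls at R-peak time + \code{morph$ptt}, and
#' adds white channel noise.
#'
#' @param subject_id Subject identifier.
#' @param morph A \code{\link{morphology_params}} object (its \code{period}
#'   is overridden by the heart rate).
#' @param duration_s,fs Record duration (s) and sampling rate (Hz).
#' @param hr_bpm Heart rate (bpm).
#' @param noise_sd_ppg,noise_sd_ecg Channel noise sd.
#' @param rr_jitter_sd Beat-to-beat RR jitter sd (s).
#' @return List with \code{recording} (a \code{\link{recording}}) and
#'   \code{beat_truth} (data.frame of true per-beat fiducial times, s).
#' @export
synthesize_recording <- function(subject_id, morph, duration_s, fs, hr_bpm,
                                 noise_sd_ppg = 0, noise_sd_ecg = 0,
                                 rr_jitter_sd = 0.005) {
  period <- 60 / hr_bpm
  n <- floor(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  r_times <- seq(0.5, duration_s - 1.2 * period, by = period)
  if (rr_jitter_sd > 0)
    r_times <- r_times + c(0, cumsum(stats::rnorm(length(r_times) - 1, 0,
                                                  rr_jitter_sd)))
  m <- morph; m$period <- period
  validate_morphology(m)
  tf <- true_fiducials(m)
  shift0 <- m$ptt - unname(tf$b1["t"])
  ecg <- add_gaussians(numeric(n), t, r_times, rep(1, length(r_times)),
                       rep(ecg_r_width, length(r_times)))
  ppg <- rep(m$baseline, n)
  truth <- vector("list", length(r_times))
  for (b in seq_along(r_times)) {
    sh <- r_times[b] + shift0
    ppg <- add_gaussians(ppg, t, m$centers + sh, m$a, m$widths)
    row <- data.frame(beat = b, r_time = r_times[b],
                      b1_t = tf$b1["t"] + sh, b0_t = tf$b0["t"] + sh,
                      sep_t = tf$sep["t"] + sh,
                      srp_t = if (is.null(tf$srp)) NA_real_ else tf$srp["t"] + sh,
                      dp_t = if (is.null(tf$dp)) NA_real_ else tf$dp["t"] + sh,
                      sep_a = tf$sep["a"],
                      srp_a = if (is.null(tf$srp)) NA_real_ else tf$srp["a"],
                      dp_a = if (is.null(tf$dp)) NA_real_ else tf$dp["a"],
                      ptt_ms = m$ptt * 1000, row.names = NULL)
    truth[[b]] <- row
  }
  if (noise_sd_ecg > 0) ecg <- ecg + stats::rnorm(n, 0, noise_sd_ecg)
  if (noise_sd_ppg > 0) ppg <- ppg + stats::rnorm(n, 0, noise_sd_ppg)
  rec <- recording(subject_id = subject_id, fs = fs, ecg = ecg, ppg = ppg)
  list(recording = rec, beat_truth = do.call(rbind, truth))
}

#' Simulate the cuff reference protocol
#'
#' Three routine cuff readings per pressure (taken 30 s apart in the
#' measurement protocol being emulated) with i.i.d. Gaussian reading noise;
#' the arithmetic mean of the three is the reference value.
#'
#' @param true_sbp,true_dbp True pressures (mmHg).
#' @param reading_sd Per-reading noise sd (mmHg), nonnegative.
#' @param seed Optional integer seed.
#' @return List with \code{sbp_readings}, \code{dbp_readings} (length 3) and
#'   \code{sbp_mean}, \code{dbp_mean}.
#' @export
simulate_cuff_readings <- function(true_sbp, true_dbp, reading_sd = 3,
                                   seed = NULL) {
  stopifnot(reading_sd >= 0, length(true_sbp) == 1, length(true_dbp) == 1)
  if (!is.null(seed)) set.seed(seed)
  s <- true_sbp + stats::rnorm(3, 0, reading_sd)
  d <- true_dbp + stats::rnorm(3, 0, reading_sd)
  list(sbp_readings = s, dbp_readings = d,
       sbp_mean = mean(s), dbp_mean = mean(d))
}

#' Generate a synthetic cohort of synchronized ECG+PPG recordings
#'
#' Draws per-subject true SBP/DBP from the truncated-normal study
#' distributions (latent correlation \code{bp_cor}; pairs with pulse
#' pressure below \code{min_pulse_pressure} are redrawn), maps SBP to the
#' true pulse transit time and DBP to the reflected-wave delay through the
#' affine couplings in \code{params}, synthesizes each subject's two-channel
#' recording, and simulates the three-reading cuff reference.
#'
#' All randomness flows from \code{params$seed} through one RNG stream in
#' subject order, so the same parameters reproduce the cohort bit for bit.
#'
#' @param params A \code{\link{cohort_params}} object.
#' @param signals If \code{FALSE}, skip waveform synthesis and return only
#'   the ground-truth and cuff tables (fast path for model-level
#'   simulation studies).
#' @return List with \code{recordings} (list of recordings, or \code{NULL}),
#'   \code{truth} (per-subject data.frame: true BP, HR, true PTT ms,
#'   reflected delay s), \code{beat_truth} (per-beat fiducial ground truth,
#'   or \code{NULL}), \code{cuff} (readings and means), and \code{params}.
#' @export
generate_cohort <- function(params = cohort_params(), signals = TRUE) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(params$seed)
  n <- params$n
  sp <- params$sbp_parent; dp <- params$dbp_parent
  # SBP comes straight from its truncated marginal; DBP is drawn
  # conditionally (latent correlation bp_cor) and only the conditional
  # component is redrawn on rejection, so the SBP marginal stays exact
  sbp <- dbp <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      z1 <- stats::rnorm(1)
      s <- sp$mu + sp$sigma * z1
      if (s >= params$sbp_range[1] && s <= params$sbp_range[2]) break
    }
    repeat {
      z2 <- stats::rnorm(1)
      d <- dp$mu + dp$sigma * (params$bp_cor * z1 +
                                 sqrt(1 - params$bp_cor^2) * z2)
      if (d >= params$dbp_range[1] && d <= params$dbp_range[2] &&
          s - d >= params$min_pulse_pressure) break
    }
    sbp[i] <- s; dbp[i] <- d
  }
  hr <- rtrunc_norm(n, params$hr_mean, params$hr_sd,
                    params$hr_range[1], params$hr_range[2])
  ptt_ms <- params$ptt_intercept + params$ptt_slope * sbp +
    (if (params$ptt_jitter_sd > 0) stats::rnorm(n, 0, params$ptt_jitter_sd)
     else 0)
  srp_delay <- params$srp_delay_intercept + params$srp_delay_slope * dbp +
    (if (params$srp_jitter_sd > 0) stats::rnorm(n, 0, params$srp_jitter_sd)
     else 0)
  truth <- data.frame(subject = seq_len(n), sbp_true = sbp, dbp_true = dbp,
                      hr_bpm = hr, ptt_ms_true = ptt_ms,
                      srp_delay_true = srp_delay)
  cuff <- vector("list", n)
  recordings <- if (signals) vector("list", n) else NULL
  beat_truth <- if (signals) vector("list", n) else NULL
  for (i in seq_len(n)) {
    cr <- simulate_cuff_readings(sbp[i], dbp[i], params$cuff_sd)
    cuff[[i]] <- data.frame(subject = i,
                            sbp_r1 = cr$sbp_readings[1],
                            sbp_r2 = cr$sbp_readings[2],
                            sbp_r3 = cr$sbp_readings[3],
                            dbp_r1 = cr$dbp_readings[1],
                            dbp_r2 = cr$dbp_readings[2],
                            dbp_r3 = cr$dbp_readings[3],
                            sbp_cuff = cr$sbp_mean, dbp_cuff = cr$dbp_mean)
    if (signals) {
      morph <- morphology_params(
        ptt = ptt_ms[i] / 1000,
        c_srp = 0.14 + srp_delay[i],
        c_dp = 0.14 + srp_delay[i] + 0.18,
        period = 60 / hr[i])
      sr <- synthesize_recording(i, morph, params$duration_s, params$fs,
                                 hr[i], params$noise_sd_ppg,
                                 params$noise_sd_ecg)
      recordings[[i]] <- sr$recording
      bt <- sr$beat_truth; bt$subject <- i
      beat_truth[[i]] <- bt
    }
  }
  list(recordings = recordings, truth = truth,
       beat_truth = if (signals) do.call(rbind, beat_truth) else NULL,
       cuff = do.call(rbind, cuff), params = params)
}
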