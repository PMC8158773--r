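test_that("R peaks are recovered exactly on clean synthetic ECG", {
  sr <- clean_record(duration_s = 30, fs = 1000, hr = 60)
  r <- detect_r_peaks(sr$recording)
  tru <- sr$beat_truth$r_time
  expect_equal(length(r), length(tru))
  expect_lt(max(abs(r - tru)), 2e-3)
  expect_true(all(diff(r) > 0))
})

test_that("flat or degenerate ECG raises a no-signal error", {
  rec <- recording("flat", 250, rep(0, 2500), rep(20, 2500))
  expect_error(detect_r_peaks(rec), "no-signal")
  dc <- recording("dc", 250, rep(0.7, 2500), rep(20, 2500))
  expect_error(detect_r_peaks(dc), "no-signal")
})

test_that("R-peak detection stays above 99% at 10 dB SNR", {
  # amplitude-1 QRS against white noise of sd 10^(-10/20)
  cp <- cohort_params(n = 4, duration_s = 60, fs = 1000, seed = 11,
                      noise_sd_ecg = 10^(-10 / 20))
  ch <- generate_cohort(cp)
  matched <- 0; total <- 0
  for (i in seq_len(4)) {
    r <- detect_r_peaks(ch$recordings[[i]])
    tru <- ch$beat_truth$r_time[ch$beat_truth$subject == i]
    d <- vapply(tru, function(t0) min(abs(r - t0)), numeric(1))
    matched <- matched + sum(d <= 0.010)
    total <- total + length(tru)
  }
  expect_gte(matched / total, 0.99)
})

test_that("segments count beats and tile the record exactly", {
  sr <- clean_record(duration_s = 180, fs = 250, hr = 60)
  rec <- sr$recording
  r <- detect_r_peaks(rec)
  beats <- segment_beats(rec, r)
  expect_true(abs(length(beats) - 179) <= 1)
  # onsets equal R-peak times; no gaps or overlaps between segments
  expect_equal(vapply(beats, `[[`, numeric(1), "r_time"),
               r[seq_along(beats)])
  starts <- vapply(beats, `[[`, numeric(1), "i_start")
  lens <- vapply(beats, function(b) length(b$ppg), numeric(1))
  expect_equal(starts[-1], (starts + lens)[-length(starts)])
  expect_error(segment_beats(rec, r[1]), "insufficient-data")
})

test_that("quality gate accepts clean beats and rejects a saturated one", {
  sr <- clean_record(duration_s = 22, fs = 500, hr = 60)
  beats <- segment_beats(sr$recording, detect_r_peaks(sr$recording))
  gated <- quality_gate(beats, 0.9)
  expect_true(all(vapply(gated, `[[`, logical(1), "accepted")))
  expect_true(all(vapply(gated, `[[`, numeric(1), "quality") > 0.99))
  # inject a saturation spike into one beat among the clean ones
  bad <- beats
  k <- 5
  bad[[k]]$ppg[20:80] <- max(bad[[k]]$ppg) * 3
  gated2 <- quality_gate(bad, 0.9)
  expect_false(gated2[[k]]$accepted)
  expect_true(all(vapply(gated2[-k], `[[`, logical(1), "accepted")))
  # threshold 0 accepts everything
  gated0 <- quality_gate(bad, 0)
  expect_true(all(vapply(gated0, `[[`, logical(1), "accepted")))
})

test_that("quality gate is monotone in its threshold", {
  sr <- clean_record(duration_s = 22, fs = 500, hr = 60)
  beats <- segment_beats(sr$recording, detect_r_peaks(sr$recording))
  beats[[3]]$ppg <- beats[[3]]$ppg + stats::rnorm(length(beats[[3]]$ppg), 0, 0.3)
  acc <- function(th) vapply(quality_gate(beats, th), `[[`, logical(1),
                             "accepted")
  a_low <- acc(0.5); a_high <- acc(0.95)
  expect_true(all(a_low | !a_high))  # raising threshold never accepts more
})

test_that("fiducials recover generator truth within 10 ms across morphologies", {
  for (m in morphology_grid()) {
    sr <- clean_record(m, duration_s = 8, fs = 1000, hr = 64)
    beats <- gated_beats(sr$recording)
    fid <- detect_fiducials(beats[[3]])
    tru <- sr$beat_truth[sr$beat_truth$beat == 3, ]
    expect_lt(abs(fid$times[["b1"]] - tru$b1_t), 0.010)
    expect_lt(abs(fid$times[["sep"]] - tru$sep_t), 0.010)
    expect_lt(abs(fid$times[["srp"]] - tru$srp_t), 0.010)
    expect_lt(abs(fid$times[["dp"]] - tru$dp_t), 0.010)
  }
})

test_that("single-Gaussian pulse puts B0 at mu - sigma within one sample", {
  m <- morphology_params(a_srp = 0, a_dp = 0, c_sep = 0.16, w_sep = 0.05)
  sr <- clean_record(m, duration_s = 8, fs = 1000, hr = 60)
  beats <- gated_beats(sr$recording)
  fid <- detect_fiducials(beats[[2]])
  tru <- sr$beat_truth[sr$beat_truth$beat == 2, ]
  expect_lt(abs(fid$times[["b0"]] - tru$b0_t), 1.5e-3)
})

test_that("detected fiducials always satisfy the ordering invariants", {
  cp <- cohort_params(n = 3, duration_s = 15, fs = 500, seed = 21)
  ch <- generate_cohort(cp)
  for (i in 1:3) {
    beats <- gated_beats(ch$recordings[[i]])
    for (b in beats[2:4]) {
      fid <- detect_fiducials(b)
      tt <- fid$times
      expect_true(tt[["b1"]] < tt[["b0"]])
      expect_true(tt[["b0"]] < tt[["sep"]])
      expect_true(tt[["sep"]] < tt[["end"]])
      expect_gte(tt[["srp"]], tt[["sep"]])
      if (!is.na(tt[["dp"]])) expect_gt(tt[["dp"]], tt[["srp"]])
      expect_true(tt[["der3"]] > tt[["b1"]] && tt[["der3"]] < tt[["end"]])
      expect_true(tt[["sepmax"]] > tt[["b1"]] && tt[["sepmax"]] < tt[["end"]])
      expect_true(all(tt[!is.na(tt)] >= b$r_time))
      expect_true(all(tt[!is.na(tt)] <= b$r_time + length(b$ppg) / b$fs))
    }
  }
})

test_that("beats without an upstroke are demoted with a fiducial failure", {
  flat <- make_beat(rep(20, 500), fs = 500)
  expect_error(detect_fiducials(flat), "fiducial-failure")
  rejected <- make_beat(rep(20, 500), fs = 500, accepted = FALSE)
  expect_error(detect_fiducials(rejected), "fiducial-failure")
})

test_that("two-component pulses decompose exactly", {
  m <- morphology_params(a_dp = 0)
  sr <- clean_record(m, duration_s = 8, fs = 500, hr = 60)
  beats <- gated_beats(sr$recording)
  dec <- decompose_waves(beats[[3]])
  expect_true(dec$reliable)
  expect_lt(dec$residual_frac, 1e-8)
  expect_equal(unname(dec$forward["amplitude"]), 1, tolerance = 0.02)
  expect_equal(unname(dec$backward["amplitude"]), 0.45, tolerance = 0.02)
  # centers: forward at the ejection peak, backward after it
  tru <- sr$beat_truth[sr$beat_truth$beat == 3, ]
  expect_lt(abs(dec$forward[["center_s"]] - tru$sep_t), 5e-3 + 2e-3)
  expect_true(dec$forward["center_s"] < dec$backward["center_s"])
})

test_that("forward amplitude dominates the backward wave on default beats", {
  sr <- clean_record(duration_s = 10, fs = 500, hr = 64)
  beats <- gated_beats(sr$recording)
  for (b in beats[2:5]) {
    dec <- decompose_waves(b)
    expect_gte(dec$forward[["amplitude"]], dec$backward[["amplitude"]])
  }
})
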