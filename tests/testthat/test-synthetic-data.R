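test_that("beat synthesis is deterministic at zero noise and under a seed", {
  m <- morphology_params()
  b1 <- synthesize_beat(m, fs = 500, noise_sd = 0)
  b2 <- synthesize_beat(m, fs = 500, noise_sd = 0)
  expect_identical(b1, b2)
  n1 <- synthesize_beat(m, fs = 500, noise_sd = 0.05, seed = 9)
  n2 <- synthesize_beat(m, fs = 500, noise_sd = 0.05, seed = 9)
  expect_identical(n1, n2)
  expect_false(identical(n1$ppg, b1$ppg))
})

test_that("degenerate single-Gaussian pulse has max upstroke slope at mu - sigma", {
  m <- morphology_params(a_srp = 0, a_dp = 0, c_sep = 0.16, w_sep = 0.05)
  tf <- true_fiducials(m)
  expect_equal(unname(tf$b0["t"]), 0.16 - 0.05, tolerance = 1e-6)
  # and on the sampled beat, within one sample
  b <- synthesize_beat(m, fs = 1000, noise_sd = 0)
  d1 <- diff(b$ppg) * 1000
  i <- which.max(d1)
  expect_lt(abs(b$time[i] - unname(b$truth$b0["t"])), 1.5e-3)
})

test_that("pulse foot lands at R + PTT within one sample", {
  for (m in list(morphology_params(ptt = 0.15), morphology_params(ptt = 0.25))) {
    b <- synthesize_beat(m, fs = 1000, noise_sd = 0)
    expect_equal(unname(b$truth$b1["t"]), b$truth$r_time + m$ptt,
                 tolerance = 1e-3)
  }
})

test_that("invalid morphologies are rejected", {
  expect_error(morphology_params(a_srp = 1.2), "smaller than ejection")
  expect_error(morphology_params(c_srp = 0.1), "strictly increasing")
  expect_error(morphology_params(ptt = 0), "strictly inside")
  expect_error(morphology_params(c_dp = 0.9, period = 0.8), "exceed the beat")
})

test_that("ground-truth fiducial times are strictly increasing within beats", {
  for (m in morphology_grid()) {
    tf <- true_fiducials(m)
    tt <- c(tf$b1["t"], tf$b0["t"], tf$sep["t"], tf$srp["t"], tf$dp["t"])
    expect_true(all(diff(tt) > 0))
  }
})

test_that("cohorts are reproducible and respect their constraints", {
  cp <- cohort_params(n = 200, seed = 12)
  c1 <- generate_cohort(cp, signals = FALSE)
  c2 <- generate_cohort(cp, signals = FALSE)
  expect_identical(c1, c2)
  expect_true(all(c1$truth$sbp_true > c1$truth$dbp_true))
  expect_true(all(c1$truth$sbp_true >= 90 & c1$truth$sbp_true <= 175))
  expect_true(all(c1$truth$dbp_true >= 54 & c1$truth$dbp_true <= 105))
})

test_that("small-cohort signals are reproducible bit for bit", {
  cp <- cohort_params(n = 2, duration_s = 10, fs = 250, seed = 4)
  c1 <- generate_cohort(cp)
  c2 <- generate_cohort(cp)
  expect_identical(c1$recordings, c2$recordings)
  expect_identical(c1$beat_truth, c2$beat_truth)
})

test_that("cohort BP moments converge to the stated distribution", {
  ch <- generate_cohort(cohort_params(n = 2000, seed = 31), signals = FALSE)
  se_m <- 18.8 / sqrt(2000)
  expect_lt(abs(mean(ch$truth$sbp_true) - 125), 3 * se_m)
  expect_lt(abs(stats::sd(ch$truth$sbp_true) - 18.8), 3 * 18.8 / sqrt(2 * 2000))
  se_d <- 12.4 / sqrt(2000)
  expect_lt(abs(mean(ch$truth$dbp_true) - 76), 3 * se_d)
  # n = 500: sample SBP mean within 2 standard errors of 125 mmHg
  ch5 <- generate_cohort(cohort_params(n = 500, seed = 8), signals = FALSE)
  expect_lt(abs(mean(ch5$truth$sbp_true) - 125), 2 * 18.8 / sqrt(500))
})

test_that("infeasible truncation is rejected", {
  expect_error(cohort_params(sbp_mean = 300, sbp_range = c(90, 175)),
               "infeasible truncation")
})

test_that("noise-free coupling is exactly invertible", {
  cp <- cohort_params(n = 1, seed = 2, ptt_jitter_sd = 0, srp_jitter_sd = 0,
                      cuff_sd = 0)
  ch <- generate_cohort(cp, signals = FALSE)
  expect_equal(cufflessbp:::inverse_coupling_sbp(ch$truth$ptt_ms_true, cp),
               ch$truth$sbp_true, tolerance = 1e-12)
  expect_equal(cufflessbp:::inverse_coupling_dbp(ch$truth$srp_delay_true, cp),
               ch$truth$dbp_true, tolerance = 1e-12)
  expect_equal(ch$cuff$sbp_cuff, ch$truth$sbp_true, tolerance = 1e-12)
})

test_that("cuff simulation follows the three-reading protocol", {
  r0 <- simulate_cuff_readings(123, 81, reading_sd = 0)
  expect_equal(r0$sbp_readings, rep(123, 3))
  expect_equal(r0$sbp_mean, 123)
  expect_equal(r0$dbp_mean, 81)
  expect_equal(mean(c(118, 122, 126)), 122)  # mean of three readings
  r1 <- simulate_cuff_readings(123, 81, reading_sd = 2, seed = 5)
  expect_length(r1$sbp_readings, 3)
  expect_equal(r1$sbp_mean, mean(r1$sbp_readings))
  expect_error(simulate_cuff_readings(120, 80, reading_sd = -1))
})

test_that("sd of the three-reading mean matches the closed form", {
  set.seed(77)
  means <- replicate(10000, mean(stats::rnorm(3, 120, 3)))
  expect_lt(abs(stats::sd(means) - 3 / sqrt(3)) / (3 / sqrt(3)), 0.05)
  # and through the generator itself
  set.seed(78)
  gm <- replicate(2000, simulate_cuff_readings(120, 80, 3)$sbp_mean)
  expect_lt(abs(stats::sd(gm) - 3 / sqrt(3)) / (3 / sqrt(3)), 0.1)
})
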