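# shared fixtures: all built in code at test time

# a clean (noise-free, jitter-free) single-subject recording plus truth
clean_record <- function(morph = morphology_params(), duration_s = 20,
                         fs = 1000, hr = 64) {
  synthesize_recording("test", morph, duration_s, fs, hr,
                       noise_sd_ppg = 0, noise_sd_ecg = 0, rr_jitter_sd = 0)
}

# gated beats of a recording
gated_beats <- function(rec, threshold = 0.9) {
  quality_gate(segment_beats(rec, detect_r_peaks(rec)), threshold)
}

# grid of pulse morphologies spanning reflected/diastolic amplitude, delay
# and transit time; 24 combinations
morphology_grid <- function() {
  g <- expand.grid(a_srp = c(0.35, 0.5, 0.65), a_dp = c(0.2, 0.3),
                   srp_d = c(0.18, 0.22), ptt = c(0.16, 0.23))
  lapply(seq_len(nrow(g)), function(i)
    morphology_params(a_srp = g$a_srp[i], a_dp = g$a_dp[i],
                      c_srp = 0.14 + g$srp_d[i],
                      c_dp = 0.14 + g$srp_d[i] + 0.22,
                      ptt = g$ptt[i]))
}

# hand-built fiducial set (times in s, amplitudes in PPG units)
make_fiducials <- function(b1 = 0.2, b0 = 0.24, sep = 0.3, der3 = 0.31,
                           sepmax = 0.33, srp = 0.45, dp = 0.6, end = 1.0,
                           a_b1 = 20, a_sep = 21, a_srp = 20.5, a_dp = 20.2,
                           baseline = 20) {
  structure(list(
    times = c(b1 = b1, b0 = b0, sep = sep, der3 = der3, sepmax = sepmax,
              srp = srp, dp = dp, end = end),
    amps = c(b1 = a_b1, b0 = (a_b1 + a_sep) / 2, sep = a_sep, der3 = a_b1,
             sepmax = a_sep - 0.1, srp = a_srp, dp = a_dp, end = a_b1),
    baseline = baseline), class = "fiducial_set")
}

# hand-built beat
make_beat <- function(ppg, fs = 1000, r_time = 0, accepted = TRUE) {
  structure(list(beat = 1L, r_time = r_time, fs = fs, ppg = ppg,
                 i_start = round(r_time * fs) + 1, quality = 1,
                 accepted = accepted), class = "beat_pair")
}

# paired reference/predicted table
make_pairs <- function(sbp_ref, sbp_pred = sbp_ref, dbp_ref = sbp_ref - 45,
                       dbp_pred = dbp_ref) {
  data.frame(sbp_ref = sbp_ref, sbp_pred = sbp_pred,
             dbp_ref = dbp_ref, dbp_pred = dbp_pred)
}
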