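test_that("the constant RR generator emits exact interval bookkeeping", {
  rr <- generate_rr(rr_gen_spec(30, 800))
  # first beat at t = 0, beats appended while the next time fits in 30 s
  expect_length(rr$rr_ms, 37)
  expect_length(rr$beat_times_s, 38)
  expect_true(all(abs(rr$rr_ms - 800) < 1e-12))
  expect_equal(max(rr$beat_times_s), 29.6)
})

test_that("generators are bit-reproducible for a fixed spec", {
  spec <- rr_gen_spec(60, 780, lf_amp_ms = 30, hf_amp_ms = 25,
                      noise_sd_ms = 12, seed = 99)
  expect_identical(generate_rr(spec), generate_rr(spec))
  rr <- generate_rr(spec)
  r1 <- render_ppg(rr, noise_sd = 0.05, seed = 7)
  r2 <- render_ppg(rr, noise_sd = 0.05, seed = 7)
  expect_identical(r1$samples, r2$samples)
  t1 <- generate_labeled_features(n_per_class = 5, seed = 4)
  t2 <- generate_labeled_features(n_per_class = 5, seed = 4)
  expect_identical(t1, t2)
})

test_that("spec invariants block non-physiologic parameter combinations", {
  expect_error(rr_gen_spec(30, 400, lf_amp_ms = 100, hf_amp_ms = 80),
               "non-physiologic")
  expect_error(render_ppg(generate_rr(rr_gen_spec(30, 500)),
                          pulse_width_s = 0.6), "shorter")
})

test_that("rendered PPG round-trips through the detection pipeline", {
  rr <- generate_rr(rr_gen_spec(30, 790, hf_amp_ms = 30, noise_sd_ms = 10,
                                seed = 6))
  clean <- render_ppg(rr, fs = 100)
  w <- window_signal(clean, 30)[[1]]
  n_clean <- length(detect_peaks(w)$peak_indices)
  # the beat at t = 0 sits on the window edge and has no rising flank
  expect_equal(n_clean,
               sum(rr$beat_times_s > 0 & rr$beat_times_s < 30))

  # DC offset and wander do not change the detected count after conditioning
  noisy <- render_ppg(rr, fs = 100, dc_offset = 10, wander_amp = 0.3,
                      wander_freq_hz = 0.05)
  w2 <- window_signal(noisy, 30)[[1]]
  expect_equal(length(detect_peaks(w2)$peak_indices), n_clean)
})

test_that("detected mean RR is sampling-rate stable (quantization bound)", {
  rr <- generate_rr(rr_gen_spec(60, 810, hf_amp_ms = 25, noise_sd_ms = 8,
                                seed = 13))
  mean_at <- function(fs) {
    rec <- render_ppg(rr, fs = fs)
    w <- window_signal(rec, 60)[[1]]
    mean(peaks_to_rr(detect_peaks(w), fs)$rr_ms)
  }
  expect_lt(abs(mean_at(100) - mean_at(500)), 10)
})

test_that("full loop recovers generator mean RR and SDNN", {
  for (seed in 1:5) {
    rr <- generate_rr(rr_gen_spec(60, 750 + 20 * seed, lf_amp_ms = 20,
                                  hf_amp_ms = 35, noise_sd_ms = 15,
                                  seed = seed))
    rec <- render_ppg(rr, fs = 100, noise_sd = 0.02, seed = seed)
    w <- window_signal(rec, 60)[[1]]
    det <- peaks_to_rr(detect_peaks(w), 100)
    expect_lt(abs(mean(det$rr_ms) - mean(rr$rr_ms)), 10)
    expect_lt(abs(sd(det$rr_ms) - sd(rr$rr_ms)) / sd(rr$rr_ms), 0.15)
  }
})

test_that("labeled feature generation is balanced and class-ordered in lf_hf", {
  tab <- generate_labeled_features(n_per_class = 30, seed = 2)
  expect_equal(nrow(tab), 90)
  expect_equal(as.integer(table(tab$label)), rep(30L, 3))
  med <- tapply(tab$lf_hf, tab$label, median)
  expect_true(med["0"] < med["1"] && med["1"] < med["2"])
  med_rr <- tapply(tab$mean_rr, tab$label, median)
  expect_true(med_rr["0"] > med_rr["1"] && med_rr["1"] > med_rr["2"])
})

test_that("the default six-phase session layout is exact", {
  plan <- phase_plan()
  expect_equal(sum(plan$duration_s), 2700)
  expect_equal(plan$class, c(0L, 1L, 0L, 2L, 0L, 0L))
  sess <- generate_session(plan, fs = 100, seed = 3)
  expect_equal(duration(sess$rec), 2700)
  expect_equal(nrow(sess$annotations), 6)
  expect_equal(sess$annotations$end_s - sess$annotations$start_s,
               plan$duration_s)
  expect_error(phase_plan(names = c("A", "A"), duration_s = c(10, 10),
                          class = c(0, 1)), "unique")
})
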