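test_that("RR alignment recovers identity and constructed beat lags", {
  set.seed(5)
  a <- rr_series(800 + rnorm(40, 0, 40))
  self <- align_rr_pairs(a, a)
  expect_equal(self$lag, 0)
  expect_equal(self$a, self$b)

  b_shift <- rr_series(c(700, 750, a$rr_ms))  # a delayed by 2 beats in b
  sh <- align_rr_pairs(a, b_shift)
  expect_equal(sh$lag, 2)
  expect_gt(cor(sh$a, sh$b), 0.999)

  expect_error(align_rr_pairs(rr_series(800 + runif(5) * 100),
                              rr_series(900 + runif(5) * 100)),
               "overlapping")
})

test_that("linear regression reproduces exact affine relations and r2 == r^2", {
  x <- 1:50
  r1 <- linear_regression(x, x)
  expect_equal(r1$slope, 1, tolerance = 1e-12)
  expect_equal(r1$intercept, 0, tolerance = 1e-9)
  expect_equal(r1$r2, 1, tolerance = 1e-12)

  r2 <- linear_regression(x, 2 * x + 3)
  expect_equal(r2$slope, 2, tolerance = 1e-12)
  expect_equal(r2$intercept, 3, tolerance = 1e-9)

  set.seed(31)
  xs <- rnorm(100)
  ys <- xs + rnorm(100, 0, 0.1 * sd(xs))
  rep3 <- linear_regression(xs, ys)
  expect_gte(rep3$r2, 0.95)
  expect_equal(rep3$r2, rep3$r^2, tolerance = 1e-12)

  expect_error(linear_regression(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("windowed Pearson matches the self- and anti-correlation limits", {
  set.seed(8)
  a <- rnorm(1000)
  expect_equal(as.numeric(windowed_pearson(a, a)), 1, tolerance = 1e-12)
  expect_equal(as.numeric(windowed_pearson(a, -a)), -1, tolerance = 1e-12)
  b <- rnorm(1000)
  expect_lt(abs(as.numeric(windowed_pearson(a, b, window = 10))), 0.15)

  const <- rep(1, 20)
  mix <- c(rnorm(10), rep(1, 10))
  r <- windowed_pearson(mix, c(rnorm(10), rep(2, 10)), window = 10)
  expect_equal(attr(r, "n_skipped"), 1)
  expect_error(windowed_pearson(const, const, window = 10), "degenerate")
})

test_that("spectrum correlation is shift-invariant and discriminates rates", {
  rr1 <- generate_rr(rr_gen_spec(60, 833, noise_sd_ms = 5, seed = 2))
  a <- render_ppg(rr1, fs = 100)
  expect_equal(spectrum_correlation(a, a), 1, tolerance = 1e-12)

  shift <- round(100 * 0.833 / 4)
  b <- ppg_record(c(a$samples[-(1:shift)], a$samples[1:shift]), fs = 100)
  expect_equal(spectrum_correlation(a, b), 1, tolerance = 1e-6)

  rr2 <- generate_rr(rr_gen_spec(60, 500, noise_sd_ms = 5, seed = 3))
  c_rec <- render_ppg(rr2, fs = 100, pulse_width_s = 0.25,
                      duration_s = duration(a))
  r_matched <- spectrum_correlation(a, b)
  r_mismatched <- spectrum_correlation(a, c_rec)
  expect_gt(r_matched, r_mismatched)
})

test_that("STFT band energies localize tones and flip at a frequency step", {
  fs <- 100
  tt <- seq(0, 60 - 1 / fs, by = 1 / fs)
  tone4 <- ppg_record(sin(2 * pi * 4 * tt), fs)
  st <- stft_spectrogram(tone4, win_s = 2)
  share <- st$band_energy$e_2_6 / (st$band_energy$e_2_6 + st$band_energy$e_6_10)
  expect_true(all(share >= 0.9))

  x_step <- c(sin(2 * pi * 4 * tt[tt < 30]), sin(2 * pi * 8 * tt[tt >= 30]))
  st2 <- stft_spectrogram(ppg_record(x_step, fs), win_s = 2)
  dominant <- st2$band_energy$e_2_6 > st2$band_energy$e_6_10
  expect_true(all(dominant[st2$t < 29]))
  expect_true(all(!dominant[st2$t > 31]))

  flat <- stft_spectrogram(ppg_record(rep(3, 6000), fs), win_s = 2)
  expect_lt(max(flat$mag[flat$f > 0.5, ]), 1e-9)
})

test_that("two-device synthetic agreement reaches high RR regression fidelity", {
  rr <- generate_rr(rr_gen_spec(120, 800, lf_amp_ms = 30, hf_amp_ms = 40,
                                noise_sd_ms = 30, seed = 44))
  ref <- render_ppg(rr, fs = 100, pulse_width_s = 0.30, noise_sd = 0.03,
                    seed = 1, duration_s = 120)
  test <- render_ppg(rr, fs = 100, pulse_width_s = 0.25, noise_sd = 0.03,
                     seed = 2, duration_s = 120)
  rep <- device_agreement(ref, test)
  expect_gte(rep$rr_regression$r2, 0.95)
  expect_lt(abs(rep$rr_regression$slope - 1), 0.05)
  # 0.1-s blocks straddle inter-pulse baseline where independent noise
  # dominates, so the mean is well under 1 but far above the null (~0)
  expect_gt(rep$mean_block_r, 0.3)
  expect_gt(as.numeric(device_agreement(ref, test,
                                        pearson_window = 50)$mean_block_r),
            0.8)
  expect_gt(rep$spectrum_r, 0.5)
})
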