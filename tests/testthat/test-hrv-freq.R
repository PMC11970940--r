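test_that("PSD integral recovers the resampled tachogram variance", {
  rr <- generate_rr(rr_gen_spec(300, 800, lf_amp_ms = 30, hf_amp_ms = 40,
                                noise_sd_ms = 15, seed = 4))
  spec <- estimate_psd(rr)
  total <- sum(diff(spec$freqs) *
                 (spec$psd[-1] + spec$psd[-length(spec$psd)]) / 2)
  expect_equal(total, spec$tacho_var, tolerance = 0.05)
})

test_that("single-tone modulation is recovered at the right frequency", {
  for (f0 in c(0.1, 0.25)) {
    rr <- generate_rr(rr_gen_spec(300, 800,
                                  lf_amp_ms = if (f0 < 0.15) 50 else 0,
                                  hf_amp_ms = if (f0 >= 0.15) 50 else 0,
                                  noise_sd_ms = 2, seed = 21))
    spec <- estimate_psd(rr)
    f_peak <- spec$freqs[which.max(spec$psd)]
    expect_lt(abs(f_peak - f0), 0.02)
  }
})

test_that("constant tachogram has essentially no power", {
  rr <- generate_rr(rr_gen_spec(120, 800))
  spec <- estimate_psd(rr)
  expect_lt(max(spec$psd[spec$freqs > 0]), 1e-12)
})

test_that("band powers, percentages and normalized units are exact on a constructed spectrum", {
  # all power concentrated around 0.2 Hz (inside HF)
  freqs <- seq(0, 0.5, by = 0.005)
  psd <- rep(0, length(freqs))
  psd[freqs >= 0.19 & freqs <= 0.21] <- 100
  spec <- structure(list(freqs = freqs, psd = psd, resample_hz = 4,
                         n_segments = 1, tacho_var = NA),
                    class = "spectral_estimate")
  fd <- frequency_domain(spec)
  expect_equal(unname(fd["hf_pct"]), 100)
  expect_equal(unname(fd["lf_nu"]), 0)
  expect_equal(unname(fd["hf_nu"]), 100)

  # equal power in one LF and one HF block: perfect symmetry
  psd2 <- rep(0, length(freqs))
  psd2[freqs >= 0.08 & freqs <= 0.10] <- 7
  psd2[freqs >= 0.25 & freqs <= 0.27] <- 7
  spec2 <- structure(list(freqs = freqs, psd = psd2, resample_hz = 4,
                          n_segments = 1, tacho_var = NA),
                     class = "spectral_estimate")
  fd2 <- frequency_domain(spec2)
  expect_equal(unname(fd2["lf_hf"]), 1, tolerance = 1e-12)
  expect_equal(unname(fd2["lf_nu"]), 50, tolerance = 1e-12)
  expect_equal(unname(fd2["hf_nu"]), 50, tolerance = 1e-12)
})

test_that("band-power recovery: >= 80% of LF+HF lands in the modulated band", {
  for (band in c("lf", "hf")) {
    rr <- generate_rr(rr_gen_spec(300, 800,
                                  lf_amp_ms = if (band == "lf") 50 else 0,
                                  hf_amp_ms = if (band == "hf") 50 else 0,
                                  noise_sd_ms = 2, seed = 33))
    fd <- frequency_domain(estimate_psd(rr))
    share <- unname(fd[band] / (fd["lf"] + fd["hf"]))
    expect_gte(share, 0.8)
  }
})

test_that("nu values sum to 100 whenever LF+HF power exists", {
  for (seed in 1:10) {
    rr <- generate_rr(rr_gen_spec(120, 800, lf_amp_ms = 10 + seed,
                                  hf_amp_ms = 30 - seed, noise_sd_ms = 8,
                                  seed = seed))
    fd <- frequency_domain(estimate_psd(rr))
    expect_equal(unname(fd["lf_nu"] + fd["hf_nu"]), 100, tolerance = 1e-9)
  }
})

test_that("degenerate spectra are flagged, not NaN", {
  freqs <- seq(0, 0.5, by = 0.01)
  spec <- structure(list(freqs = freqs, psd = rep(0, length(freqs)),
                         resample_hz = 4, n_segments = 1, tacho_var = 0),
                    class = "spectral_estimate")
  fd <- frequency_domain(spec)
  expect_true("zero_tf" %in% attr(fd, "flags"))
  expect_false(any(is.nan(fd)))
  expect_error(frequency_domain(structure(list(freqs = seq(0, 0.2, 0.01),
                                               psd = rep(1, 21)),
                                          class = "spectral_estimate")),
               "0.4")
})

test_that("Welch estimate matches the direct-DFT oracle on single-segment records", {
  for (seed in 1:5) {
    rr <- generate_rr(rr_gen_spec(100, 820, lf_amp_ms = 25, hf_amp_ms = 35,
                                  noise_sd_ms = 10, seed = seed))
    spec <- estimate_psd(rr)
    orc <- oracle_psd(rr$rr_ms, rr$beat_times_s)
    expect_equal(spec$freqs, orc$freqs, tolerance = 1e-12)
    expect_equal(spec$psd, orc$psd, tolerance = 1e-9)
  }
})
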