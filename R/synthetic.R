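#' Specification for a synthetic RR series
#'
#' The generator models autonomic modulation as two sinusoids on the RR
#' tachogram — one in the LF band (default 0.1 Hz, sympathetic+baroreflex)
#' and one in the HF band (default 0.25 Hz, respiratory sinus arrhythmia) —
#' plus white Gaussian jitter. The invariant
#' `mean_rr - (lf_amp + hf_amp + 4 * noise_sd) > 250` keeps every interval
#' physiologic.
#'
#' @param duration_s Total duration in seconds.
#' @param mean_rr_ms Mean RR interval, ms.
#' @param lf_amp_ms,lf_freq_hz LF modulation amplitude (ms) and frequency (Hz).
#' @param hf_amp_ms,hf_freq_hz HF modulation amplitude (ms) and frequency (Hz).
#' @param noise_sd_ms SD of additive white interval noise, ms.
#' @param seed Integer RNG seed.
#' @return An object of class `rr_gen_spec`.
#' @export
rr_gen_spec <- function(duration_s, mean_rr_ms = 800,
                        lf_amp_ms = 0, lf_freq_hz = 0.1,
                        hf_amp_ms = 0, hf_freq_hz = 0.25,
                        noise_sd_ms = 0, seed = 1L) {
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  if (mean_rr_ms - (lf_amp_ms + hf_amp_ms + 4 * noise_sd_ms) <= 250) {
    stop("spec would produce non-physiologic intervals (< 250 ms possible)",
         call. = FALSE)
  }
  structure(list(duration_s = duration_s, mean_rr_ms = mean_rr_ms,
                 lf_amp_ms = lf_amp_ms, lf_freq_hz = lf_freq_hz,
                 hf_amp_ms = hf_amp_ms, hf_freq_hz = hf_freq_hz,
                 noise_sd_ms = noise_sd_ms, seed = as.integer(seed)),
            class = "rr_gen_spec")
}

#' Generate a synthetic RR series with controlled spectral structure
#'
#' Beat times are built iteratively from t = 0: the interval opened at beat
#' time t_k is
#' `mean + lf_amp * sin(2 pi lf_freq t_k) + hf_amp * sin(2 pi hf_freq t_k) + N(0, noise_sd)`,
#' and beats are appended while the next beat time stays within the duration.
#' Deterministic for a given spec (the seed is part of the spec).
#'
#' @param spec An [rr_gen_spec()].
#' @return An [rr_series()] with exact beat times.
#' @export
generate_rr <- function(spec) {
  stopifnot(inherits(spec, "rr_gen_spec"))
  set.seed(spec$seed)
  t <- 0
  times <- t
  rr <- numeric(0)
  repeat {
    iv <- spec$mean_rr_ms +
      spec$lf_amp_ms * sin(2 * pi * spec$lf_freq_hz * t) +
      spec$hf_amp_ms * sin(2 * pi * spec$hf_freq_hz * t) +
      stats::rnorm(1L, 0, spec$noise_sd_ms)
    t_next <- t + iv / 1000
    if (t_next > spec$duration_s) break
    rr <- c(rr, iv)
    times <- c(times, t_next)
    t <- t_next
  }
  rr_series(rr, beat_times_s = times)
}

#' Render a synthetic PPG waveform from an RR series
#'
#' Places one asymmetric unit-amplitude pulse (fast Gaussian rise, slower
#' Gaussian decay — a crude systolic upstroke/diastolic runoff shape) at each
#' beat time, then adds a DC offset, sinusoidal baseline wander and white
#' noise. The pulse peak falls exactly on the beat time, so detected peaks
#' recover the generator's beat grid up to sample quantization.
#'
#' @param rr An [rr_series()].
#' @param fs Sampling rate in Hz (>= 50).
#' @param pulse_width_s Overall pulse width in seconds; must be shorter than
#'   the shortest RR interval or pulses would merge.
#' @param wander_amp,wander_freq_hz Baseline-wander amplitude (same units as
#'   the pulse, i.e. fractions of the unit peak) and frequency (Hz).
#' @param noise_sd SD of additive white noise.
#' @param dc_offset Constant offset.
#' @param duration_s Length of the rendered record in seconds; defaults to
#'   the last beat time plus one pulse width, rounded up to a whole second
#'   (so a record generated from an N-second RR spec spans N seconds).
#' @param seed Integer RNG seed.
#' @return A [ppg_record()] spanning the RR series' beat times.
#' @export
render_ppg <- function(rr, fs = 100, pulse_width_s = 0.35,
                       wander_amp = 0, wander_freq_hz = 0.05,
                       noise_sd = 0, dc_offset = 0, duration_s = NULL,
                       seed = 1L) {
  stopifnot(inherits(rr, "rr_series"))
  if (fs < 50) stop("fs must be >= 50 Hz", call. = FALSE)
  if (length(rr$rr_ms) && pulse_width_s * 1000 >= min(rr$rr_ms)) {
    stop("pulse_width_s must be shorter than the shortest RR interval",
         call. = FALSE)
  }
  dur <- if (is.null(duration_s)) ceiling(max(rr$beat_times_s) + pulse_width_s)
         else duration_s
  n <- round(dur * fs)
  tt <- (seq_len(n) - 1L) / fs
  x <- numeric(n)
  s_rise <- 0.12 * pulse_width_s
  s_decay <- 0.25 * pulse_width_s
  for (tb in rr$beat_times_s) {
    i0 <- max(1L, floor((tb - 4 * s_rise) * fs) + 1L)
    i1 <- min(n, ceiling((tb + 4 * s_decay) * fs) + 1L)
    tau <- tt[i0:i1] - tb
    sig <- ifelse(tau < 0, s_rise, s_decay)
    x[i0:i1] <- x[i0:i1] + exp(-tau^2 / (2 * sig^2))
  }
  set.seed(seed)
  x <- x + dc_offset + wander_amp * sin(2 * pi * wander_freq_hz * tt) +
    stats::rnorm(n, 0, noise_sd)
  ppg_record(x, fs = fs)
}

#' Class profiles for the three stress states
#'
#' Each profile maps a stress label to ranges of RR-generator parameters.
#' The defaults encode the two most robust physiological directions of acute
#' mental stress: mean RR falls (heart rate rises) and the LF/HF modulation
#' amplitude ratio rises from class 0 (none: mean 800 ms, LF 20 / HF 40 ms)
#' through class 1 (moderate: 760, 35/30) to class 2 (severe: 720, 50/18),
#' with 10 ms interval noise throughout. Per-window draws jitter the mean by
#' +-30 ms and scale both amplitudes by a factor in [0.8, 1.2].
#'
#' @param susceptibility Optional subject-level shift in [0, 1]: scales the
#'   whole profile toward the stressed direction (mean RR lowered by up to
#'   60 ms, LF amplitude raised and HF lowered by up to 30%), modelling
#'   stable between-subject differences in stress reactivity.
#' @return List of three `class_profile` objects (labels 0, 1, 2).
#' @export
default_class_profiles <- function(susceptibility = 0) {
  base <- list(
    list(label = 0L, mean_rr = 800, lf_amp = 20, hf_amp = 40),
    list(label = 1L, mean_rr = 760, lf_amp = 35, hf_amp = 30),
    list(label = 2L, mean_rr = 720, lf_amp = 50, hf_amp = 18))
  lapply(base, function(p) {
    structure(list(
      label = p$label,
      mean_rr_range = p$mean_rr - 60 * susceptibility + c(-30, 30),
      lf_amp_range = p$lf_amp * (1 + 0.3 * susceptibility) * c(0.8, 1.2),
      hf_amp_range = p$hf_amp * (1 - 0.3 * susceptibility) * c(0.8, 1.2),
      noise_sd_ms = 10), class = "class_profile")
  })
}

draw_spec_from_profile <- function(profile, duration_s, seed) {
  set.seed(seed)
  rr_gen_spec(duration_s = duration_s,
              mean_rr_ms = stats::runif(1, profile$mean_rr_range[1L],
                                        profile$mean_rr_range[2L]),
              lf_amp_ms = stats::runif(1, profile$lf_amp_range[1L],
                                       profile$lf_amp_range[2L]),
              hf_amp_ms = stats::runif(1, profile$hf_amp_range[1L],
                                       profile$hf_amp_range[2L]),
              noise_sd_ms = profile$noise_sd_ms,
              seed = as.integer((as.numeric(seed) * 7) %% 2147483647))
}

#' Generate a labeled three-class HRV feature table
#'
#' Emulates a labeled training corpus: for each class, window-level
#' RR-generator specs are drawn from the class profile, an RR series is
#' generated, and [extract_features()] produces one labeled row. Windows
#' that come out invalid are regenerated with a fresh sub-seed (at most 10
#' attempts each).
#'
#' @param profiles List of class profiles (see [default_class_profiles()]).
#' @param n_per_class Rows per class.
#' @param window_s Window duration per row, seconds.
#' @param seed Integer RNG seed.
#' @param cfg A [run_config()].
#' @return Balanced labeled feature table with `3 * n_per_class` rows.
#' @export
generate_labeled_features <- function(profiles = default_class_profiles(),
                                      n_per_class = 200, window_s = 30,
                                      seed = 1L, cfg = run_config()) {
  if (n_per_class < 1) stop("n_per_class must be >= 1", call. = FALSE)
  vectors <- list()
  labels <- integer(0)
  counter <- 0L
  for (profile in profiles) {
    for (i in seq_len(n_per_class)) {
      counter <- counter + 1L
      v <- NULL
      for (attempt in 1:10) {
        sub_seed <- (as.numeric(seed) * 100003 + counter * 131 + attempt) %%
          2147483647
        spec <- draw_spec_from_profile(profile, window_s, sub_seed)
        v <- extract_features(generate_rr(spec), cfg)
        if (isTRUE(attr(v, "valid"))) break
      }
      if (!isTRUE(attr(v, "valid"))) {
        stop(sprintf("profile for class %d keeps producing invalid windows",
                     profile$label), call. = FALSE)
      }
      vectors[[counter]] <- v
      labels <- c(labels, profile$label)
    }
  }
  feature_table(vectors, labels = labels)
}

#' Six-phase stress-protocol plan
#'
#' The default plan mirrors a standard Stroop stress protocol: Rest 1
#' (5 min baseline, class 0), Stroop 1 (5 min, moderate stress, class 1),
#' Rest 2 (10 min recovery, class 0), Stroop 2 (5 min with auditory
#' interference, severe stress, class 2), Rest 3 (10 min recovery, class 0),
#' Relax (10 min guided relaxation, class 0).
#'
#' @param names Phase names (unique).
#' @param duration_s Phase durations in seconds (> 0).
#' @param class True stress class per phase (0, 1 or 2).
#' @return Data frame of class `phase_plan` with `name`, `duration_s`,
#'   `class`, `start_s`, `end_s`.
#' @export
phase_plan <- function(names = c("Rest 1", "Stroop 1", "Rest 2", "Stroop 2",
                                 "Rest 3", "Relax"),
                       duration_s = c(300, 300, 600, 300, 600, 600),
                       class = c(0L, 1L, 0L, 2L, 0L, 0L)) {
  if (anyDuplicated(names)) stop("phase names must be unique", call. = FALSE)
  if (any(duration_s <= 0)) stop("phase durations must be > 0", call. = FALSE)
  if (any(!class %in% 0:2)) stop("phase classes must be 0, 1 or 2", call. = FALSE)
  ends <- cumsum(duration_s)
  structure(data.frame(name = names, duration_s = duration_s,
                       class = as.integer(class),
                       start_s = ends - duration_s, end_s = ends,
                       stringsAsFactors = FALSE),
            class = c("phase_plan", "data.frame"))
}

#' Generate a full synthetic protocol session
#'
#' Renders one subject's continuous PPG recording for a [phase_plan()]:
#' each phase draws an RR-generator spec from the profile of its true class,
#' generates the RR series, renders the PPG, and the per-phase records are
#' concatenated. Phase annotations carry name, start/end and true class.
#'
#' @param plan A [phase_plan()].
#' @param fs Sampling rate, Hz.
#' @param seed Integer RNG seed.
#' @param profiles Class profiles (subject-specific profiles model
#'   between-subject reactivity; see [default_class_profiles()]).
#' @param noise_sd,wander_amp,dc_offset Rendering noise parameters passed to
#'   [render_ppg()].
#' @return List with `rec` (a [ppg_record()]) and `annotations` (the plan
#'   data frame).
#' @export
generate_session <- function(plan = phase_plan(), fs = 100, seed = 1L,
                             profiles = default_class_profiles(),
                             noise_sd = 0.02, wander_amp = 0.3,
                             dc_offset = 1) {
  stopifnot(inherits(plan, "phase_plan"))
  prof_by_label <- stats::setNames(profiles,
                                   vapply(profiles, `[[`, integer(1), "label"))
  samples <- numeric(0)
  for (i in seq_len(nrow(plan))) {
    sub_seed <- (as.numeric(seed) * 48271 + i * 1009) %% 2147483647
    profile <- prof_by_label[[as.character(plan$class[i])]]
    spec <- draw_spec_from_profile(profile, plan$duration_s[i], sub_seed)
    rr <- generate_rr(spec)
    rec <- render_ppg(rr, fs = fs, noise_sd = noise_sd,
                      wander_amp = wander_amp, dc_offset = dc_offset,
                      seed = sub_seed)
    nkeep <- round(plan$duration_s[i] * fs)
    ph <- rec$samples
    ph <- if (length(ph) >= nkeep) ph[seq_len(nkeep)] else
      c(ph, rep(dc_offset, nkeep - length(ph)))
    samples <- c(samples, ph)
  }
  list(rec = ppg_record(samples, fs = fs), annotations = plan)
}
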