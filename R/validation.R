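#' Align two RR series by beat index
#'
#' Two devices recording the same heart emit nearly identical RR sequences,
#' but may miss or add beats at the start. The second series is offset by the
#' integer lag (searched over +-`max_lag` beats) maximizing the
#' cross-correlation of the two interval sequences, then both are truncated
#' to their common length.
#'
#' @param a,b [rr_series()] objects (or numeric RR vectors in ms).
#' @param max_lag Maximum beat lag searched.
#' @param min_overlap Minimum number of overlapping beats after alignment.
#' @return List with `a`, `b` (equal-length numeric vectors) and `lag`
#'   (the applied offset of `b` relative to `a`).
#' @export
align_rr_pairs <- function(a, b, max_lag = 5, min_overlap = 10) {
  xa <- rr_values(a); xb <- rr_values(b)
  if (!length(xa) || !length(xb)) stop("both series must be non-empty",
                                       call. = FALSE)
  best <- NULL
  for (lag in -max_lag:max_lag) {
    ia <- seq_along(xa)
    ib <- ia + lag
    ok <- ib >= 1L & ib <= length(xb)
    if (sum(ok) < 3L) next
    va <- xa[ia[ok]]; vb <- xb[ib[ok]]
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
      score <- -sum((va - vb)^2)  # degenerate: fall back to agreement
    } else {
      score <- stats::cor(va, vb)
    }
    if (is.null(best) || score > best$score ||
        (score == best$score && abs(lag) < abs(best$lag))) {
      best <- list(score = score, lag = lag, a = va, b = vb)
    }
  }
  if (is.null(best) || length(best$a) < min_overlap) {
    stop(sprintf("fewer than %d overlapping beats after alignment", min_overlap),
         call. = FALSE)
  }
  list(a = best$a, b = best$b, lag = best$lag)
}

#' Ordinary least-squares agreement regression
#'
#' Simple linear regression of `y` on `x` with the Pearson correlation and
#' coefficient of determination; for this one-predictor case `r2` equals
#' `r^2` exactly.
#'
#' @param x,y Paired numeric vectors, n >= 3, `var(x) > 0`.
#' @return A `regression_report`: `slope`, `intercept`, `r`, `r2`, `n`.
#' @export
linear_regression <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::var(x) == 0) stop("x has zero variance", call. = FALSE)
  fit <- stats::lm(y ~ x)
  r <- stats::cor(x, y)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r = r, r2 = r^2, n = length(x)),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("<regression_report> y = %.4f x + %.4f | r = %.4f, r2 = %.4f (n = %d)\n",
              x$slope, x$intercept, x$r, x$r2, x$n))
  invisible(x)
}

#' Mean windowed Pearson correlation of two overlaid signals
#'
#' Splits both signals into consecutive non-overlapping blocks of `window`
#' points and averages the per-block Pearson correlations. Blocks where
#' either signal is constant are skipped (count reported via the
#' `n_skipped` attribute).
#'
#' @param a,b Equal-length numeric vectors.
#' @param window Block length in points (>= 3; default 10).
#' @return Mean block correlation, with attributes `n_blocks`, `n_skipped`.
#' @export
windowed_pearson <- function(a, b, window = 10) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("signals must have equal length", call. = FALSE)
  if (window < 3) stop("window must be >= 3 points", call. = FALSE)
  n_blocks <- floor(length(a) / window)
  if (n_blocks < 1L) stop("signals shorter than one window", call. = FALSE)
  rs <- vapply(seq_len(n_blocks), function(k) {
    i <- ((k - 1L) * window + 1L):(k * window)
    if (stats::sd(a[i]) == 0 || stats::sd(b[i]) == 0) return(NA_real_)
    stats::cor(a[i], b[i])
  }, numeric(1))
  skipped <- sum(is.na(rs))
  if (skipped == n_blocks) stop("all blocks degenerate (zero variance)",
                                call. = FALSE)
  out <- mean(rs, na.rm = TRUE)
  attr(out, "n_blocks") <- n_blocks
  attr(out, "n_skipped") <- skipped
  out
}

#' Correlation of two FFT magnitude spectra
#'
#' Both records are transformed with the FFT; the shorter one is zero-padded
#' so the two magnitude spectra share a frequency grid, which is then
#' restricted to 0-`fmax` Hz (default 10 Hz, covering pulsatile PPG content)
#' before the Pearson correlation. Magnitudes are invariant to time shifts,
#' so phase offsets between devices do not matter.
#'
#' @param a,b [ppg_record()] objects with equal sampling rates and durations
#'   within 1%.
#' @param fmax Upper frequency bound of the compared band, Hz.
#' @return Pearson correlation of the two magnitude spectra.
#' @export
spectrum_correlation <- function(a, b, fmax = 10) {
  stopifnot(inherits(a, "ppg_record"), inherits(b, "ppg_record"))
  if (a$fs != b$fs) stop("sampling rates differ", call. = FALSE)
  if (abs(duration(a) - duration(b)) > 0.01 * max(duration(a), duration(b))) {
    stop("durations differ by more than 1%", call. = FALSE)
  }
  n <- max(length(a$samples), length(b$samples))
  pad <- function(x) c(x - mean(x), rep(0, n - length(x)))
  ma <- Mod(stats::fft(pad(a$samples)))
  mb <- Mod(stats::fft(pad(b$samples)))
  freqs <- (seq_len(n) - 1L) * a$fs / n
  keep <- freqs <= fmax & seq_len(n) <= floor(n / 2) + 1L
  stats::cor(ma[keep], mb[keep])
}

#' Short-time Fourier transform of a PPG record
#'
#' Hann-windowed STFT magnitude (via \code{signal::specgram}) plus the
#' per-segment mean band energies in 2-6 Hz and 6-10 Hz, the bands used to
#' summarise pulsatile signal intensity in time-frequency analyses.
#'
#' @param rec A [ppg_record()].
#' @param win_s Segment length in seconds.
#' @param overlap Fractional overlap between segments in [0, 1).
#' @return List of class `stft_result`: `t` (segment centre times, s), `f`
#'   (Hz), `mag` (|STFT|, frequencies x segments), and `band_energy`, a data
#'   frame with per-segment mean energy in the 2-6 and 6-10 Hz bands.
#' @export
stft_spectrogram <- function(rec, win_s = 2, overlap = 0.5) {
  stopifnot(inherits(rec, "ppg_record"))
  if (duration(rec) < 2 * win_s) {
    stop("record must span at least two STFT windows", call. = FALSE)
  }
  nwin <- round(win_s * rec$fs)
  noverlap <- floor(overlap * nwin)
  sg <- signal::specgram(rec$samples - mean(rec$samples), n = nwin,
                         Fs = rec$fs, window = signal::hanning(nwin),
                         overlap = noverlap)
  mag <- Mod(sg$S)
  f <- as.numeric(sg$f)
  band_mean <- function(lo, hi) {
    rows <- f >= lo & f <= hi
    colMeans(mag[rows, , drop = FALSE]^2)
  }
  structure(list(t = as.numeric(sg$t), f = f, mag = mag,
                 band_energy = data.frame(t = as.numeric(sg$t),
                                          e_2_6 = band_mean(2, 6),
                                          e_6_10 = band_mean(6, 10))),
            class = "stft_result")
}

#' @export
print.stft_result <- function(x, ...) {
  cat(sprintf("<stft_result> %d segments x %d frequencies (to %.1f Hz)\n",
              ncol(x$mag), nrow(x$mag), max(x$f)))
  invisible(x)
}

#' Cross-device agreement report
#'
#' Convenience wrapper running the full agreement battery on two
#' simultaneously recorded PPG signals: per-device beat detection and RR
#' regression, overlaid windowed Pearson correlation of the conditioned
#' signals, and FFT spectrum correlation.
#'
#' @param ref,test [ppg_record()] objects from the two devices.
#' @param cfg A [run_config()].
#' @param pearson_window Block size for [windowed_pearson()].
#' @return List: `rr_regression` (a `regression_report`), `mean_block_r`,
#'   `spectrum_r`, `lag_beats`.
#' @export
device_agreement <- function(ref, test, cfg = run_config(),
                             pearson_window = 10) {
  rr_of <- function(rec) {
    wins <- window_signal(rec, window_s = duration(rec),
                          cutoff_hz = cfg$cutoff_hz, order = cfg$filter_order)
    beats <- detect_peaks(wins[[1L]], threshold = cfg$peak_threshold,
                          refractory_ms = cfg$refractory_ms)
    list(rr = peaks_to_rr(beats, rec$fs), win = wins[[1L]])
  }
  ra <- rr_of(ref); rb <- rr_of(test)
  pairs <- align_rr_pairs(ra$rr, rb$rr)
  n <- min(length(ra$win$samples), length(rb$win$samples))
  list(rr_regression = linear_regression(pairs$a, pairs$b),
       mean_block_r = as.numeric(windowed_pearson(ra$win$samples[1:n],
                                                  rb$win$samples[1:n],
                                                  window = pearson_window)),
       spectrum_r = spectrum_correlation(ref, test),
       lag_beats = pairs$lag)
}
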