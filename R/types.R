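#' Construct a PPG record
#'
#' A `ppg_record` holds a uniformly sampled photoplethysmogram: raw amplitudes
#' in arbitrary ADC units together with the sampling rate. It is the container
#' every downstream step (filtering, windowing, beat detection) consumes.
#'
#' @param samples Numeric vector of finite amplitudes, length >= 1.
#' @param fs Sampling rate in Hz, > 0.
#' @param t0 Start time of the first sample in seconds (default 0).
#'
#' @return An object of class `ppg_record` with elements `samples`, `fs`, `t0`.
#' @examples
#' rec <- ppg_record(sin(2 * pi * 1.2 * seq(0, 10, by = 0.01)), fs = 100)
#' duration(rec)
#' @export
ppg_record <- function(samples, fs, t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    stop("'samples' must contain at least one value", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    bad <- which(!is.finite(samples))[1L]
    stop(sprintf("non-finite sample at position %d", bad), call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("'fs' must be a single positive number (Hz)", call. = FALSE)
  }
  structure(list(samples = samples, fs = as.numeric(fs), t0 = as.numeric(t0)),
            class = "ppg_record")
}

#' Duration of a PPG record in seconds
#' @param rec A `ppg_record`.
#' @return Duration in seconds (`length(samples) / fs`).
#' @export
duration <- function(rec) {
  stopifnot(inherits(rec, "ppg_record"))
  length(rec$samples) / rec$fs
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf("<ppg_record> %d samples @ %g Hz (%.2f s, t0 = %g s)\n",
              length(x$samples), x$fs, duration(x), x$t0))
  invisible(x)
}

#' Construct an RR-interval series
#'
#' Beat-to-beat (RR) intervals in milliseconds, with the absolute time of each
#' beat in seconds. For `n` beats there are `n - 1` intervals.
#'
#' @param rr_ms Numeric vector of RR intervals in ms, all > 0.
#' @param beat_times_s Optional beat times in seconds (length `length(rr_ms) + 1`).
#'   If omitted, beats are placed at the cumulative interval sums from 0.
#'
#' @return An object of class `rr_series`.
#' @export
rr_series <- function(rr_ms, beat_times_s = NULL) {
  rr_ms <- as.numeric(rr_ms)
  if (length(rr_ms) && any(!is.finite(rr_ms) | rr_ms <= 0)) {
    stop("all RR intervals must be finite and > 0 ms", call. = FALSE)
  }
  if (is.null(beat_times_s)) {
    beat_times_s <- cumsum(c(0, rr_ms)) / 1000
  }
  beat_times_s <- as.numeric(beat_times_s)
  if (length(beat_times_s) != length(rr_ms) + 1L) {
    stop("'beat_times_s' must have one more element than 'rr_ms'", call. = FALSE)
  }
  structure(list(rr_ms = rr_ms, beat_times_s = beat_times_s),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  n <- length(x$rr_ms)
  if (n == 0L) {
    cat("<rr_series> empty\n")
  } else {
    cat(sprintf("<rr_series> %d intervals, mean %.1f ms (HR %.1f bpm), span %.1f s\n",
                n, mean(x$rr_ms), 60000 / mean(x$rr_ms),
                x$beat_times_s[n + 1L] - x$beat_times_s[1L]))
  }
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$rr_ms)

#' Canonical HRV feature names
#'
#' The fixed, ordered names of the 34 HRV parameters computed per analysis
#' window: 11 time-domain, 8 relative time-domain, 11 frequency-domain and 4
#' nonlinear parameters. Feature tables, trained models and predictions all
#' use this ordering.
#'
#' @return Character vector of length 34.
#' @export
hrv_feature_names <- function() {
  c("mean_rr", "median_rr", "sdnn", "rmssd", "sdsd", "sdnn_rmssd", "hr",
    "pnn25", "pnn50", "kurt", "skew",
    "rel_mean_rr", "rel_median_rr", "rel_sdnn", "rel_rmssd", "rel_sdsd",
    "rel_sdnn_rmssd", "rel_kurt", "rel_skew",
    "vlf", "vlf_pct", "lf", "lf_pct", "lf_nu", "hf", "hf_pct", "hf_nu",
    "tf", "lf_hf", "hf_lf",
    "sd1", "sd2", "sampen", "higuchi")
}
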