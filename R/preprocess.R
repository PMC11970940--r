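#' Zero-phase Butterworth high-pass filter
#'
#' Removes the DC level and slow baseline wander from a raw PPG trace with a
#' Butterworth high-pass (default 0.5 Hz) applied forward and backward, so
#' beat timings are not shifted by filter phase. Reflected (odd) padding at
#' both ends suppresses startup transients inside short analysis windows.
#'
#' @param x Numeric amplitude vector.
#' @param fs Sampling rate in Hz.
#' @param cutoff High-pass cutoff in Hz; must lie in (0, fs/2).
#' @param order Butterworth order (the forward-backward pass doubles the
#'   effective attenuation).
#' @return Filtered vector of the same length as `x`.
#' @examples
#' y <- highpass(rep(5, 400), fs = 100, cutoff = 0.5)
#' max(abs(y[50:350])) # ~ 0: DC removed
#' @export
highpass <- function(x, fs, cutoff = 0.5, order = 2) {
  x <- as.numeric(x)
  if (cutoff <= 0 || cutoff >= fs / 2) {
    stop(sprintf("cutoff must lie strictly between 0 and fs/2 = %g Hz", fs / 2),
         call. = FALSE)
  }
  n <- length(x)
  if (n <= 27L) {
    stop("input too short to filter (need > 27 samples)", call. = FALSE)
  }
  # pad generously relative to the filter's time constant (~fs/cutoff samples)
  # so startup transients decay inside the padding, not the window
  npad <- min(n - 1L, ceiling(3 * fs / cutoff))
  bf <- signal::butter(order, cutoff / (fs / 2), type = "high")
  # odd reflection about the end points, as in standard zero-phase practice
  head_pad <- 2 * x[1L] - x[(npad + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - npad)]
  xp <- c(head_pad, x, tail_pad)
  y <- signal::filter(bf, xp)
  y <- rev(as.numeric(signal::filter(bf, rev(as.numeric(y)))))
  y[(npad + 1L):(npad + n)]
}

#' Normalize a window to the [-1, 1] amplitude scale
#'
#' Divides the window by its maximum absolute value, so the largest excursion
#' is exactly +-1 and the fixed 0.5 peak threshold is meaningful across
#' recordings. An all-zero window cannot be normalized; it is returned
#' unchanged with attribute `valid = FALSE` rather than producing NaN.
#'
#' @param x Numeric vector.
#' @return `x / max(abs(x))`, carrying attribute `valid`.
#' @export
normalize_amplitude <- function(x) {
  x <- as.numeric(x)
  if (!length(x)) stop("cannot normalize an empty window", call. = FALSE)
  m <- max(abs(x))
  if (m == 0) {
    attr(x, "valid") <- FALSE
    return(x)
  }
  out <- x / m
  attr(out, "valid") <- TRUE
  out
}

#' Cut a PPG record into conditioned analysis windows
#'
#' Splits the record into fixed-length windows (default 30 s, non-overlapping)
#' and conditions each one independently: high-pass filter, then normalize to
#' [-1, 1]. A trailing partial window is dropped. Each element of the result
#' is a `signal_window` with `samples`, `fs`, `start_s` and a `valid` flag
#' (FALSE for all-zero/flatline windows).
#'
#' @param rec A [ppg_record()].
#' @param window_s Window length in seconds.
#' @param step_s Step between window starts in seconds.
#' @param cutoff_hz High-pass cutoff in Hz.
#' @param order Butterworth order.
#' @return List of `signal_window` objects.
#' @export
window_signal <- function(rec, window_s = 30, step_s = window_s,
                          cutoff_hz = 0.5, order = 2) {
  stopifnot(inherits(rec, "ppg_record"))
  if (duration(rec) < window_s) {
    stop(sprintf("record (%.1f s) shorter than one window (%g s)",
                 duration(rec), window_s), call. = FALSE)
  }
  wlen <- round(window_s * rec$fs)
  step <- round(step_s * rec$fs)
  starts <- seq(0L, length(rec$samples) - wlen, by = step)
  lapply(starts, function(s0) {
    raw <- rec$samples[(s0 + 1L):(s0 + wlen)]
    start_s <- rec$t0 + s0 / rec$fs
    if (max(abs(raw - raw[1L])) == 0) {
      # flatline: filtering would return ~0 everywhere and normalization fail
      return(structure(list(samples = raw * 0, fs = rec$fs, start_s = start_s,
                            valid = FALSE), class = "signal_window"))
    }
    filt <- highpass(raw, rec$fs, cutoff = cutoff_hz, order = order)
    norm <- normalize_amplitude(filt)
    structure(list(samples = as.numeric(norm), fs = rec$fs, start_s = start_s,
                   valid = isTRUE(attr(norm, "valid"))),
              class = "signal_window")
  })
}

#' @export
print.signal_window <- function(x, ...) {
  cat(sprintf("<signal_window> %d samples @ %g Hz, start %.1f s, %s\n",
              length(x$samples), x$fs, x$start_s,
              if (x$valid) "valid" else "INVALID"))
  invisible(x)
}
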