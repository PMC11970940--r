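#' Detect systolic peaks in a conditioned PPG window
#'
#' A peak is a local maximum whose normalized amplitude reaches the threshold
#' (default 0.5 on the [-1, 1] scale). A refractory period (default 250 ms,
#' capping heart rate at 240 bpm) suppresses double detections on dicrotic
#' notches: of two candidates closer than the refractory interval, the taller
#' one is kept. Before localization the trace is lightly smoothed with a
#' short moving average (default 50 ms, well under the systolic upstroke
#' time), the usual guard against sample-level noise pulling the argmax off
#' the true peak; indices remain integer sample positions, with no
#' sub-sample interpolation.
#'
#' @param window A `signal_window` from [window_signal()], or a plain numeric
#'   vector already normalized (then `fs` must be given).
#' @param threshold Minimum normalized amplitude of a peak.
#' @param refractory_ms Minimum separation between accepted peaks in ms.
#' @param smooth_ms Moving-average width for peak localization, ms; 0
#'   disables smoothing.
#' @param fs Sampling rate, only needed when `window` is a bare vector.
#' @return A `beat_series` with `peak_indices` (1-based sample indices,
#'   strictly increasing) and `peak_times_s` (relative to the window start).
#'   An invalid window yields an empty series with a warning.
#' @export
detect_peaks <- function(window, threshold = 0.5, refractory_ms = 250,
                         smooth_ms = 50, fs = NULL) {
  if (inherits(window, "signal_window")) {
    if (!window$valid) {
      warning("invalid window: returning empty beat series", call. = FALSE)
      return(structure(list(peak_indices = integer(0), peak_times_s = numeric(0)),
                       class = "beat_series"))
    }
    x <- window$samples
    fs <- window$fs
  } else {
    x <- as.numeric(window)
    if (is.null(fs)) stop("'fs' is required for a bare numeric window",
                          call. = FALSE)
  }
  n <- length(x)
  k <- max(1L, round(smooth_ms / 1000 * fs))
  if (k > 1L) {
    if (k %% 2L == 0L) k <- k + 1L  # odd width keeps the peak centred
    x <- stats::filter(x, rep(1 / k, k), sides = 2)
    x[is.na(x)] <- 0
    x <- as.numeric(x)
  }
  # local maxima: strictly rising into the peak, non-increasing after
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= threshold]
  min_gap <- refractory_ms / 1000 * fs
  keep <- integer(0)
  for (i in cand) {
    if (!length(keep) || i - keep[length(keep)] >= min_gap) {
      keep <- c(keep, i)
    } else if (x[i] > x[keep[length(keep)]]) {
      keep[length(keep)] <- i
    }
  }
  structure(list(peak_indices = keep, peak_times_s = (keep - 1L) / fs),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d peaks\n", length(x$peak_indices)))
  invisible(x)
}

#' Convert detected peaks to RR intervals
#'
#' Adjacent peak indices are differenced and scaled by the sampling rate:
#' `rr_ms[i] = (peak[i+1] - peak[i]) / fs * 1000`. Peaks are integer sample
#' indices, so RR values are quantized at `1000/fs` ms.
#'
#' @param beats A `beat_series`.
#' @param fs Sampling rate in Hz.
#' @return An [rr_series()]; fewer than two peaks yield an empty series with
#'   attribute `insufficient = TRUE`.
#' @export
peaks_to_rr <- function(beats, fs) {
  stopifnot(inherits(beats, "beat_series"))
  if (length(beats$peak_indices) < 2L) {
    out <- rr_series(numeric(0))
    attr(out, "insufficient") <- TRUE
    return(out)
  }
  rr <- diff(beats$peak_indices) / fs * 1000
  rr_series(rr, beat_times_s = (beats$peak_indices - 1L) / fs)
}

#' Remove non-physiologic RR intervals
#'
#' Drops intervals outside `[lo_ms, hi_ms]` (defaults 300-2000 ms, i.e. 30-200
#' bpm). Disabled with `lo_ms = 0, hi_ms = Inf`, in which case the input is
#' returned verbatim. The number of removals is reported via the
#' `n_removed` attribute.
#'
#' @param rr An [rr_series()].
#' @param lo_ms,hi_ms Inclusive physiologic bounds in ms.
#' @return A cleaned [rr_series()] (beat times recomputed from the retained
#'   intervals) with attribute `n_removed`.
#' @export
clean_rr <- function(rr, lo_ms = 300, hi_ms = 2000) {
  stopifnot(inherits(rr, "rr_series"))
  if (lo_ms == 0 && is.infinite(hi_ms)) {
    attr(rr, "n_removed") <- 0L
    return(rr)
  }
  keep <- rr$rr_ms >= lo_ms & rr$rr_ms <= hi_ms
  out <- rr_series(rr$rr_ms[keep])
  attr(out, "n_removed") <- sum(!keep)
  out
}
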