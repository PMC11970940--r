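#' Time-domain HRV parameters
#'
#' Computes the 11 time-domain statistics of one RR window: mean and median
#' RR (ms), SDNN (sample SD of intervals), RMSSD (root mean square of
#' successive differences), SDSD (sample SD of successive differences), the
#' SDNN/RMSSD ratio, heart rate (60000 / mean RR, bpm), pNN25 and pNN50
#' (percentage of successive differences exceeding 25 / 50 ms), excess
#' kurtosis and skewness.
#'
#' For a constant series RMSSD is 0 and the SDNN/RMSSD ratio is undefined; it
#' is reported as 0 with attribute `constant_series = TRUE`.
#'
#' @param rr An [rr_series()] or numeric vector of intervals in ms; >= 4
#'   intervals required (skewness/kurtosis need them).
#' @return Named numeric vector of the 11 parameters.
#' @examples
#' time_domain(c(800, 850, 780, 820))
#' @export
time_domain <- function(rr) {
  x <- rr_values(rr)
  if (length(x) < 4L) stop("time-domain HRV needs >= 4 intervals", call. = FALSE)
  d <- diff(x)
  sdnn <- stats::sd(x)
  rmssd <- sqrt(mean(d^2))
  sdsd <- stats::sd(d)
  constant <- rmssd == 0
  out <- c(mean_rr = mean(x),
           median_rr = stats::median(x),
           sdnn = sdnn,
           rmssd = rmssd,
           sdsd = sdsd,
           sdnn_rmssd = if (constant) 0 else sdnn / rmssd,
           hr = 60000 / mean(x),
           pnn25 = 100 * mean(abs(d) > 25),
           pnn50 = 100 * mean(abs(d) > 50),
           kurt = if (sdnn == 0) 0 else e1071::kurtosis(x, type = 1),
           skew = if (sdnn == 0) 0 else e1071::skewness(x, type = 1))
  if (constant) attr(out, "constant_series") <- TRUE
  out
}

#' Relative time-domain HRV parameters
#'
#' The same statistics recomputed on the mean-normalized intervals
#' `u_i = rr_i / mean(rr) - 1`, which removes between-subject differences in
#' baseline heart rate. `rel_mean_rr` is identically 0 by construction, and
#' `rel_sdnn` equals the coefficient of variation SDNN / mean RR.
#'
#' @inheritParams time_domain
#' @return Named numeric vector of the 8 relative parameters.
#' @export
relative_time_domain <- function(rr) {
  x <- rr_values(rr)
  if (length(x) < 4L) stop("relative time-domain HRV needs >= 4 intervals",
                           call. = FALSE)
  if (mean(x) <= 0) stop("mean RR must be positive", call. = FALSE)
  u <- x / mean(x) - 1
  d <- diff(u)
  sdnn <- stats::sd(u)
  rmssd <- sqrt(mean(d^2))
  constant <- rmssd == 0
  out <- c(rel_mean_rr = mean(u),
           rel_median_rr = stats::median(u),
           rel_sdnn = sdnn,
           rel_rmssd = rmssd,
           rel_sdsd = stats::sd(d),
           rel_sdnn_rmssd = if (constant) 0 else sdnn / rmssd,
           rel_kurt = if (sdnn == 0) 0 else e1071::kurtosis(u, type = 1),
           rel_skew = if (sdnn == 0) 0 else e1071::skewness(u, type = 1))
  if (constant) attr(out, "constant_series") <- TRUE
  out
}

# accept rr_series or bare numeric
rr_values <- function(rr) {
  if (inherits(rr, "rr_series")) rr$rr_ms else as.numeric(rr)
}

rr_times <- function(rr) {
  if (inherits(rr, "rr_series")) rr$beat_times_s else cumsum(c(0, as.numeric(rr))) / 1000
}
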