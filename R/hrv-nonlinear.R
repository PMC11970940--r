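#' Poincare plot descriptors SD1 and SD2
#'
#' Dispersion of the lag-1 return map (rr_i, rr_i+1) perpendicular and
#' parallel to the identity line: `sd1 = SD(diff(rr)) / sqrt(2)` (short-term
#' variability) and `sd2 = sqrt(2 * SDNN^2 - SDSD^2 / 2)` (long-term
#' variability). A numerically negative argument under the square root
#' (possible only through rounding) is clipped to 0 and flagged.
#'
#' @param rr An [rr_series()] or numeric RR vector in ms; >= 3 intervals.
#' @return Named numeric vector `c(sd1, sd2)` in ms.
#' @export
poincare <- function(rr) {
  x <- rr_values(rr)
  if (length(x) < 3L) stop("Poincare descriptors need >= 3 intervals",
                           call. = FALSE)
  sdsd <- stats::sd(diff(x))
  sd1 <- sdsd / sqrt(2)
  arg <- 2 * stats::sd(x)^2 - sdsd^2 / 2
  clipped <- arg < 0
  out <- c(sd1 = sd1, sd2 = sqrt(max(arg, 0)))
  if (clipped) attr(out, "clipped") <- TRUE
  out
}

#' Sample entropy of an RR series
#'
#' SampEn(m, r) = -ln(A / B), where B counts pairs of length-`m` templates
#' (i != j, self-matches excluded) whose Chebyshev distance is strictly below
#' the tolerance r, and A counts the same at length m + 1. The tolerance is
#' `r_factor` times the sample SD of the series (defaults m = 2,
#' r_factor = 0.2). Low values indicate regular, predictable rhythms; white
#' noise scores high.
#'
#' @param rr An [rr_series()] or numeric vector; needs >= m + 2 intervals and
#'   positive variance.
#' @param m Template (embedding) length.
#' @param r_factor Tolerance as a multiple of the sample SD.
#' @return Sample entropy in nats. A zero-variance series is undefined:
#'   returns 0 with attribute `undefined = TRUE`. If no length-(m+1) matches
#'   exist (A = 0), returns `Inf` with attribute `no_matches = TRUE`.
#' @export
sample_entropy <- function(rr, m = 2, r_factor = 0.2) {
  x <- rr_values(rr)
  n <- length(x)
  if (n < m + 2L) stop(sprintf("sample entropy needs >= %d intervals", m + 2L),
                       call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) {
    out <- 0
    attr(out, "undefined") <- TRUE
    return(out)
  }
  r <- r_factor * s
  # length-m templates restricted to the first n-m positions so A and B use
  # the same template set (canonical SampEn); pairwise Chebyshev distance as
  # a running max over lagged differences, self-matches excluded
  count_pairs <- function(mm, nv) {
    dmax <- matrix(0, nv, nv)
    for (k in 0:(mm - 1L)) {
      v <- x[(1L + k):(nv + k)]
      dmax <- pmax(dmax, abs(outer(v, v, "-")))
    }
    (sum(dmax < r) - nv) / 2
  }
  nB <- n - m
  B <- count_pairs(m, nB)
  A <- count_pairs(m + 1L, nB)
  if (B == 0) {
    out <- 0
    attr(out, "undefined") <- TRUE
    return(out)
  }
  if (A == 0) {
    out <- Inf
    attr(out, "no_matches") <- TRUE
    return(out)
  }
  -log(A / B)
}

#' Higuchi fractal dimension of an RR series
#'
#' Standard Higuchi construction on the beat-indexed sequence: for each
#' coarse-graining factor k = 1..kmax, average the normalized curve length
#' L(k) over the k possible offsets; the fractal dimension is the negative
#' slope of the least-squares fit of ln L(k) on ln k. Smooth series approach
#' 1, uncorrelated noise approaches 2.
#'
#' @param rr An [rr_series()] or numeric vector; needs >= 2 * kmax values.
#' @param kmax Maximum coarse-graining factor (default 8, suited to ~35-beat
#'   30-s windows). If the series is too short, kmax is reduced to
#'   `floor(n / 2)` with a warning.
#' @return Estimated fractal dimension (typically in [1, 2]).
#' @export
higuchi_fd <- function(rr, kmax = 8) {
  x <- rr_values(rr)
  n <- length(x)
  if (n < 2L * kmax) {
    kmax <- floor(n / 2)
    warning(sprintf("series too short; reducing kmax to %d", kmax),
            call. = FALSE)
  }
  if (kmax < 2L) stop("series too short for Higuchi's method", call. = FALSE)
  Lk <- numeric(kmax)
  for (k in seq_len(kmax)) {
    lm_sum <- 0
    for (m0 in seq_len(k)) {
      idx <- seq(m0, n, by = k)
      ni <- length(idx) - 1L
      if (ni < 1L) next
      # normalization maps the subsampled length back to the original scale
      lm_sum <- lm_sum + sum(abs(diff(x[idx]))) * (n - 1) / (ni * k) / k
    }
    Lk[k] <- lm_sum / k
  }
  ok <- Lk > 0
  if (sum(ok) < 2L) {
    out <- 1
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  fit <- stats::lm.fit(cbind(1, log(seq_len(kmax)[ok])), log(Lk[ok]))
  -unname(fit$coefficients[2L])
}
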