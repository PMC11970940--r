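# Independent brute-force oracles used to cross-check the package's HRV
# statistics. These deliberately avoid the implementation's code paths:
# plain loops, explicit moment sums, direct O(n^2) template counting and a
# direct DFT instead of the FFT-based Welch estimator.

oracle_moments <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  list(mean = mu, m2 = m2, m3 = m3, m4 = m4,
       sd = sqrt(sum((x - mu)^2) / (n - 1)),
       skew = m3 / m2^1.5, kurt = m4 / m2^2 - 3)
}

oracle_time_domain <- function(rr) {
  d <- rr[-1] - rr[-length(rr)]
  mo <- oracle_moments(rr)
  srt <- sort(rr)
  n <- length(rr)
  med <- if (n %% 2 == 1) srt[(n + 1) / 2] else (srt[n / 2] + srt[n / 2 + 1]) / 2
  rmssd <- sqrt(sum(d^2) / length(d))
  sdsd <- oracle_moments(d)$sd
  c(mean_rr = mo$mean, median_rr = med, sdnn = mo$sd, rmssd = rmssd,
    sdsd = sdsd, sdnn_rmssd = if (rmssd == 0) 0 else mo$sd / rmssd,
    hr = 60000 / mo$mean,
    pnn25 = 100 * sum(abs(d) > 25) / length(d),
    pnn50 = 100 * sum(abs(d) > 50) / length(d),
    kurt = mo$kurt, skew = mo$skew)
}

oracle_relative_time_domain <- function(rr) {
  u <- rr / (sum(rr) / length(rr)) - 1
  td <- oracle_time_domain(u * 1)  # reuse arithmetic on the normalized scale
  c(rel_mean_rr = unname(td["mean_rr"]), rel_median_rr = unname(td["median_rr"]),
    rel_sdnn = unname(td["sdnn"]), rel_rmssd = unname(td["rmssd"]),
    rel_sdsd = unname(td["sdsd"]), rel_sdnn_rmssd = unname(td["sdnn_rmssd"]),
    rel_kurt = unname(td["kurt"]), rel_skew = unname(td["skew"]))
}

# Poincare via explicit 45-degree rotation of the lag-1 return map
oracle_poincare <- function(rr) {
  n <- length(rr)
  x1 <- rr[1:(n - 1)]; x2 <- rr[2:n]
  p1 <- (x2 - x1) / sqrt(2)   # perpendicular to identity line
  c(sd1 = oracle_moments(p1)$sd,
    sd2 = sqrt(max(2 * oracle_moments(rr)$m2 * n / (n - 1) -
                     oracle_moments(x2 - x1)$sd^2 / 2, 0)))
}

# O(n^2) double-loop sample entropy, templates restricted to n - m
oracle_sampen <- function(x, m = 2, r_factor = 0.2) {
  n <- length(x)
  r <- r_factor * oracle_moments(x)$sd
  count <- function(mm) {
    nv <- n - m
    tot <- 0L
    for (i in 1:(nv - 1)) {
      for (j in (i + 1):nv) {
        dmax <- 0
        for (k in 0:(mm - 1)) {
          dmax <- max(dmax, abs(x[i + k] - x[j + k]))
        }
        if (dmax < r) tot <- tot + 1L
      }
    }
    tot
  }
  B <- count(m)
  A <- count(m + 1)
  if (B == 0) return(NA_real_)
  if (A == 0) return(Inf)
  -log(A / B)
}

# straightforward re-implementation of Higuchi's curve-length construction
oracle_higuchi <- function(x, kmax = 8) {
  n <- length(x)
  lnL <- c(); lnk <- c()
  for (k in 1:kmax) {
    Ls <- c()
    for (m0 in 1:k) {
      pts <- x[seq(m0, n, by = k)]
      np <- length(pts) - 1
      if (np < 1) next
      L <- 0
      for (i in 1:np) L <- L + abs(pts[i + 1] - pts[i])
      Ls <- c(Ls, L * (n - 1) / (np * k) / k)
    }
    Lk <- mean(Ls)
    if (Lk > 0) { lnL <- c(lnL, log(Lk)); lnk <- c(lnk, log(k)) }
  }
  xb <- mean(lnk); yb <- mean(lnL)
  -sum((lnk - xb) * (lnL - yb)) / sum((lnk - xb)^2)
}

# direct-DFT single-segment Hann periodogram of the spline-resampled
# tachogram (valid when the record fits in one Welch segment)
oracle_psd <- function(rr_ms, beat_times_s, resample_hz = 4) {
  tt <- beat_times_s[-1]
  grid <- seq(tt[1], tt[length(tt)], by = 1 / resample_hz)
  y <- stats::spline(tt, rr_ms, xout = grid, method = "fmm")$y
  y <- y - sum(y) / length(y)
  N <- length(y)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(N - 1)) / (N - 1))
  yw <- y * w
  nf <- floor(N / 2) + 1
  j <- 0:(N - 1)
  psd <- numeric(nf)
  for (kk in 0:(nf - 1)) {
    re <- sum(yw * cos(2 * pi * kk * j / N))
    im <- -sum(yw * sin(2 * pi * kk * j / N))
    p <- (re^2 + im^2) / (resample_hz * sum(w^2))
    dbl <- if (kk == 0 || (N %% 2 == 0 && kk == N / 2)) 1 else 2
    psd[kk + 1] <- p * dbl
  }
  list(freqs = (0:(nf - 1)) * resample_hz / N, psd = psd)
}

oracle_band_power <- function(freqs, psd, lo, hi) {
  lo <- max(lo, freqs[1]); hi <- min(hi, freqs[length(freqs)])
  if (hi <= lo) return(0)
  fx <- sort(unique(c(lo, freqs[freqs > lo & freqs < hi], hi)))
  fy <- stats::approx(freqs, psd, xout = fx)$y
  tot <- 0
  for (i in 1:(length(fx) - 1)) {
    tot <- tot + (fx[i + 1] - fx[i]) * (fy[i] + fy[i + 1]) / 2
  }
  tot
}

oracle_frequency_domain <- function(freqs, psd) {
  vlf <- oracle_band_power(freqs, psd, 0.003, 0.04)
  lf <- oracle_band_power(freqs, psd, 0.04, 0.15)
  hf <- oracle_band_power(freqs, psd, 0.15, 0.4)
  tf <- vlf + lf + hf
  c(vlf = vlf, vlf_pct = 100 * vlf / tf, lf = lf, lf_pct = 100 * lf / tf,
    lf_nu = 100 * lf / (tf - vlf), hf = hf, hf_pct = 100 * hf / tf,
    hf_nu = 100 * hf / (tf - vlf), tf = tf, lf_hf = lf / hf, hf_lf = hf / lf)
}

# random physiologic RR series for oracle sweeps
random_rr <- function(n, seed, mean_ms = 850, sd_ms = 60) {
  set.seed(seed)
  rr_series(mean_ms + stats::rnorm(n, 0, sd_ms))
}
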