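#' Power spectral density of the RR tachogram
#'
#' The irregularly sampled tachogram (RR value at the time of each closing
#' beat) is interpolated with a cubic spline onto a uniform grid (default
#' 4 Hz), mean-removed, and its one-sided PSD estimated by Welch's method
#' with Hann-windowed segments: a single full-length segment for short
#' (e.g. 30-s) windows, 120-s segments with 50% overlap for long recordings.
#' Units are ms^2/Hz, so band integrals are in ms^2.
#'
#' @param rr An [rr_series()] (beat times are used) or numeric RR vector in
#'   ms (beats then assumed contiguous from time 0).
#' @param resample_hz Tachogram resampling rate in Hz.
#' @param seg_s Welch segment length in seconds for long recordings.
#' @return An object of class `spectral_estimate`: list with `freqs` (Hz),
#'   `psd` (ms^2/Hz), `resample_hz`, `n_segments`.
#' @export
estimate_psd <- function(rr, resample_hz = 4, seg_s = 120) {
  x <- rr_values(rr)
  tt <- rr_times(rr)[-1L]  # interval i closes at beat i+1
  if (length(x) < 4L || (tt[length(tt)] - tt[1L]) < 10) {
    stop("spectral estimation needs >= 4 beats spanning >= 10 s", call. = FALSE)
  }
  grid <- seq(tt[1L], tt[length(tt)], by = 1 / resample_hz)
  y <- stats::spline(tt, x, xout = grid, method = "fmm")$y
  y <- y - mean(y)
  n <- length(y)
  seg_len <- min(n, round(seg_s * resample_hz))
  step <- max(1L, floor(seg_len / 2))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, seg_len - 1) / (seg_len - 1))
  scale <- resample_hz * sum(w^2)
  nf <- floor(seg_len / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- y[s:(s + seg_len - 1L)] * w
    sp <- Mod(stats::fft(seg))^2 / scale
    p <- sp[seq_len(nf)]
    # one-sided: double everything except DC (and Nyquist when seg_len even)
    dbl <- rep(2, nf)
    dbl[1L] <- 1
    if (seg_len %% 2 == 0) dbl[nf] <- 1
    acc <- acc + p * dbl
  }
  psd <- acc / length(starts)
  structure(list(freqs = (seq_len(nf) - 1L) * resample_hz / seg_len,
                 psd = psd, resample_hz = resample_hz,
                 n_segments = length(starts),
                 tacho_var = stats::var(y) * (n - 1) / n),
            class = "spectral_estimate")
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf("<spectral_estimate> %d bins to %.2f Hz (df = %.4f Hz, %d segment%s)\n",
              length(x$freqs), max(x$freqs), x$freqs[2L] - x$freqs[1L],
              x$n_segments, if (x$n_segments > 1) "s" else ""))
  invisible(x)
}

# trapezoidal band integral with interpolated band edges
band_power <- function(freqs, psd, lo, hi) {
  if (hi <= freqs[1L] || lo >= freqs[length(freqs)]) return(0)
  lo <- max(lo, freqs[1L]); hi <- min(hi, freqs[length(freqs)])
  inside <- freqs > lo & freqs < hi
  fx <- c(lo, freqs[inside], hi)
  fy <- c(stats::approx(freqs, psd, xout = lo)$y, psd[inside],
          stats::approx(freqs, psd, xout = hi)$y)
  sum(diff(fx) * (fy[-1L] + fy[-length(fy)]) / 2)
}

#' Frequency-domain HRV parameters
#'
#' Integrates the tachogram PSD over the VLF (0.003-0.04 Hz), LF
#' (0.04-0.15 Hz) and HF (0.15-0.4 Hz) bands (trapezoidal rule with
#' interpolated band edges). Total power TF is the band sum VLF + LF + HF,
#' so the band percentages sum to 100. Normalized units remove the VLF
#' share: `lf_nu = 100 * lf / (tf - vlf)` and likewise for HF, so
#' lf_nu + hf_nu = 100 whenever LF + HF > 0.
#'
#' @param spec A `spectral_estimate` from [estimate_psd()].
#' @param vlf,lf,hf Two-element band edges in Hz.
#' @return Named numeric vector of the 11 frequency-domain parameters, with
#'   attribute `flags` naming any undefined ratios (reported as 0): `zero_tf`
#'   when all bands are empty, `zero_hf` / `zero_lf` for the LF/HF and HF/LF
#'   ratios.
#' @export
frequency_domain <- function(spec, vlf = c(0.003, 0.04), lf = c(0.04, 0.15),
                             hf = c(0.15, 0.4)) {
  stopifnot(inherits(spec, "spectral_estimate"))
  if (max(spec$freqs) < hf[2L]) {
    stop(sprintf("spectrum must extend to %g Hz (covers only %g Hz)",
                 hf[2L], max(spec$freqs)), call. = FALSE)
  }
  p_vlf <- band_power(spec$freqs, spec$psd, vlf[1L], vlf[2L])
  p_lf <- band_power(spec$freqs, spec$psd, lf[1L], lf[2L])
  p_hf <- band_power(spec$freqs, spec$psd, hf[1L], hf[2L])
  tf <- p_vlf + p_lf + p_hf
  flags <- character(0)
  if (tf == 0) {
    flags <- "zero_tf"
    pct <- c(0, 0, 0); nu <- c(0, 0); ratios <- c(0, 0)
  } else {
    pct <- 100 * c(p_vlf, p_lf, p_hf) / tf
    denom <- tf - p_vlf
    nu <- if (denom > 0) 100 * c(p_lf, p_hf) / denom else {
      flags <- c(flags, "zero_lf_hf_total"); c(0, 0)
    }
    ratios <- c(if (p_hf > 0) p_lf / p_hf else {
                  flags <- c(flags, "zero_hf"); 0
                },
                if (p_lf > 0) p_hf / p_lf else {
                  flags <- c(flags, "zero_lf"); 0
                })
  }
  out <- c(vlf = p_vlf, vlf_pct = pct[1L], lf = p_lf, lf_pct = pct[2L],
           lf_nu = nu[1L], hf = p_hf, hf_pct = pct[3L], hf_nu = nu[2L],
           tf = tf, lf_hf = ratios[1L], hf_lf = ratios[2L])
  if (length(flags)) attr(out, "flags") <- flags
  out
}
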