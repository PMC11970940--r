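#' Extract the full 34-parameter HRV feature vector from one RR window
#'
#' Runs [time_domain()], [relative_time_domain()], [estimate_psd()] +
#' [frequency_domain()], [poincare()], [sample_entropy()] and [higuchi_fd()]
#' on a single window's RR series and assembles the canonical 34-element
#' feature vector (see [hrv_feature_names()] for order).
#'
#' A window with fewer than `cfg$min_beats` beats, or whose spectral
#' estimation fails, is marked invalid (`valid` attribute FALSE) rather than
#' producing a partial row. Undefined ratios (constant series, empty bands)
#' are reported as 0 and the responsible flags are collected in the `flags`
#' attribute. Inside short 30-s windows the VLF band lies below the spectral
#' resolution; `"vlf_unresolved"` is flagged in that case.
#'
#' @param rr An [rr_series()].
#' @param cfg A [run_config()]; band edges, SampEn and Higuchi settings and
#'   the minimum beat count come from here.
#' @return Named numeric vector of length 34 with attributes `valid` (logical)
#'   and `flags` (character). Invalid windows return NA values with
#'   `valid = FALSE`.
#' @export
extract_features <- function(rr, cfg = run_config()) {
  stopifnot(inherits(rr, "rr_series"))
  invalid <- function(reason) {
    out <- stats::setNames(rep(NA_real_, 34L), hrv_feature_names())
    attr(out, "valid") <- FALSE
    attr(out, "flags") <- reason
    out
  }
  n_beats <- length(rr$rr_ms) + 1L
  if (length(rr$rr_ms) == 0L || n_beats < cfg$min_beats) {
    return(invalid("too_few_beats"))
  }
  flags <- character(0)
  td <- time_domain(rr)
  if (isTRUE(attr(td, "constant_series"))) flags <- c(flags, "constant_series")
  rtd <- relative_time_domain(rr)
  spec <- tryCatch(estimate_psd(rr, resample_hz = cfg$resample_hz),
                   error = function(e) NULL)
  if (is.null(spec)) return(invalid("spectral_estimation_failed"))
  fd <- frequency_domain(spec, vlf = cfg$vlf, lf = cfg$lf, hf = cfg$hf)
  flags <- c(flags, attr(fd, "flags"))
  # Hann mainlobe spans ~2 bins; the VLF band is unresolved when that
  # exceeds the band width (always the case for 30-s windows)
  df_res <- spec$freqs[2L] - spec$freqs[1L]
  if (2 * df_res > cfg$vlf[2L] - cfg$vlf[1L]) flags <- c(flags, "vlf_unresolved")
  pc <- poincare(rr)
  se <- sample_entropy(rr, m = cfg$sampen_m, r_factor = cfg$sampen_r_factor)
  if (isTRUE(attr(se, "undefined"))) flags <- c(flags, "sampen_undefined")
  if (isTRUE(attr(se, "no_matches"))) {
    # no template pair survives at length m+1: SampEn is right-censored; use
    # its finite upper bound (one matching pair among all possible pairs) so
    # the feature row stays usable for modeling
    flags <- c(flags, "sampen_capped")
    n_t <- length(rr$rr_ms) - cfg$sampen_m
    se <- -log(2 / (n_t * (n_t - 1)))
  }
  hig <- suppressWarnings(higuchi_fd(rr, kmax = cfg$higuchi_kmax))
  out <- c(td, rtd, fd[c("vlf", "vlf_pct", "lf", "lf_pct", "lf_nu",
                         "hf", "hf_pct", "hf_nu", "tf", "lf_hf", "hf_lf")],
           pc, sampen = as.numeric(se), higuchi = as.numeric(hig))
  out <- out[hrv_feature_names()]
  attr(out, "valid") <- TRUE
  attr(out, "flags") <- flags
  out
}

#' Assemble feature vectors into a feature table
#'
#' Stacks a list of feature vectors from [extract_features()] into a
#' validated data frame, dropping invalid windows, and optionally attaches a
#' label column.
#'
#' @param vectors List of 34-element feature vectors.
#' @param labels Optional integer labels in {0, 1, 2}, one per vector
#'   (recycled if length 1); labels of dropped (invalid) vectors are dropped
#'   too.
#' @return Feature-table data frame (34 columns, plus `label` if given).
#' @export
feature_table <- function(vectors, labels = NULL) {
  valid <- vapply(vectors, function(v) isTRUE(attr(v, "valid")), logical(1))
  if (!is.null(labels)) labels <- rep_len(labels, length(vectors))[valid]
  rows <- lapply(vectors[valid], function(v) as.data.frame(as.list(unclass(v))))
  tab <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    as.data.frame(stats::setNames(rep(list(numeric(0)), 34L),
                                  hrv_feature_names()))
  }
  if (!is.null(labels)) tab$label <- as.integer(labels)
  validate_feature_table(tab)
  tab
}
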