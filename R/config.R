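#' Pipeline run configuration
#'
#' Collects every tunable constant of the PPG-to-stress pipeline in one
#' validated object. Defaults reproduce the reference pipeline: 30-s analysis
#' windows recomputed every 30 s, a 0.5 Hz zero-phase Butterworth high-pass,
#' per-window normalization to [-1, 1] with a 0.5 peak threshold, 100 Hz
#' sampling, standard VLF/LF/HF band edges, SampEn with m = 2 and
#' r = 0.2 * SD, Higuchi kmax = 8, and a CART with max depth 10, minimum
#' split size 10 and minimum leaf size 5.
#'
#' @param window_s Analysis window length in seconds.
#' @param step_s Step between window starts in seconds.
#' @param cutoff_hz High-pass cutoff in Hz (must be < `fs`/2).
#' @param filter_order Butterworth order for the high-pass (applied
#'   forward-backward, so the effective order doubles).
#' @param peak_threshold Peak-detection threshold on the normalized [-1, 1]
#'   amplitude scale.
#' @param refractory_ms Minimum separation between detected peaks in ms.
#' @param fs Default sampling rate in Hz.
#' @param vlf,lf,hf Two-element band edges in Hz; must be strictly increasing
#'   end to end.
#' @param resample_hz Uniform tachogram resampling rate for spectral
#'   estimation, in Hz.
#' @param sampen_m Sample-entropy embedding length.
#' @param sampen_r_factor Sample-entropy tolerance as a multiple of the SD.
#' @param higuchi_kmax Maximum coarse-graining factor for Higuchi's method.
#' @param min_beats Minimum beats per window for a valid feature vector.
#' @param rr_lo_ms,rr_hi_ms Optional physiologic RR bounds used by
#'   [clean_rr()]; cleaning is off by default in the pipeline.
#' @param tree A [tree_hyperparams()] object.
#' @param seed Integer RNG seed used by stochastic helpers.
#'
#' @return An object of class `run_config`.
#' @examples
#' cfg <- run_config(window_s = 10)
#' cfg$window_s
#' @export
run_config <- function(window_s = 30, step_s = 30, cutoff_hz = 0.5,
                       filter_order = 2, peak_threshold = 0.5,
                       refractory_ms = 250, fs = 100,
                       vlf = c(0.003, 0.04), lf = c(0.04, 0.15),
                       hf = c(0.15, 0.4), resample_hz = 4,
                       sampen_m = 2, sampen_r_factor = 0.2,
                       higuchi_kmax = 8, min_beats = 10,
                       rr_lo_ms = 300, rr_hi_ms = 2000,
                       tree = tree_hyperparams(), seed = 1L) {
  cfg <- list(window_s = window_s, step_s = step_s, cutoff_hz = cutoff_hz,
              filter_order = filter_order, peak_threshold = peak_threshold,
              refractory_ms = refractory_ms, fs = fs,
              vlf = vlf, lf = lf, hf = hf, resample_hz = resample_hz,
              sampen_m = sampen_m, sampen_r_factor = sampen_r_factor,
              higuchi_kmax = higuchi_kmax, min_beats = min_beats,
              rr_lo_ms = rr_lo_ms, rr_hi_ms = rr_hi_ms,
              tree = tree, seed = as.integer(seed))
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  with(cfg, {
    if (window_s <= 0) stop("window_s must be > 0", call. = FALSE)
    if (step_s <= 0) stop("step_s must be > 0", call. = FALSE)
    if (fs <= 0) stop("fs must be > 0", call. = FALSE)
    if (cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
      stop(sprintf("cutoff_hz must satisfy 0 < cutoff_hz < fs/2 (= %g Hz)", fs / 2),
           call. = FALSE)
    }
    edges <- c(vlf, lf, hf)
    if (length(edges) != 6L || any(diff(c(vlf[1], vlf[2], lf[2], hf[2])) <= 0) ||
        vlf[2] != lf[1] || lf[2] != hf[1]) {
      stop("band edges must be contiguous and strictly increasing", call. = FALSE)
    }
    if (sampen_m < 1) stop("sampen_m must be >= 1", call. = FALSE)
    if (sampen_r_factor <= 0) stop("sampen_r_factor must be > 0", call. = FALSE)
    if (higuchi_kmax < 2) stop("higuchi_kmax must be >= 2", call. = FALSE)
  })
  invisible(cfg)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(paste0("<run_config> window %g s / step %g s, fs %g Hz, ",
                     "high-pass %g Hz (order %d), peak threshold %g\n"),
              x$window_s, x$step_s, x$fs, x$cutoff_hz, x$filter_order,
              x$peak_threshold))
  cat(sprintf("  bands VLF %g-%g, LF %g-%g, HF %g-%g Hz; resample %g Hz\n",
              x$vlf[1], x$vlf[2], x$lf[1], x$lf[2], x$hf[1], x$hf[2],
              x$resample_hz))
  invisible(x)
}

#' Decision-tree hyperparameters
#'
#' Hyperparameters of the three-class CART stress model: maximum depth 10,
#' minimum samples to split an internal node 10, minimum samples per leaf 5.
#'
#' @param max_depth Maximum tree depth (>= 1).
#' @param min_samples_split Minimum rows required to attempt a split (>= 2).
#' @param min_samples_leaf Minimum rows in any leaf (>= 1).
#' @param split_criterion Impurity criterion; `"gini"` or `"information"`.
#' @param seed Integer seed recorded with the model for reproducibility.
#'
#' @return An object of class `tree_hyperparams`.
#' @export
tree_hyperparams <- function(max_depth = 10, min_samples_split = 10,
                             min_samples_leaf = 5, split_criterion = "gini",
                             seed = 1L) {
  if (max_depth < 1) stop("max_depth must be >= 1", call. = FALSE)
  if (min_samples_split < 2) stop("min_samples_split must be >= 2", call. = FALSE)
  if (min_samples_leaf < 1) stop("min_samples_leaf must be >= 1", call. = FALSE)
  split_criterion <- match.arg(split_criterion, c("gini", "information"))
  structure(list(max_depth = as.integer(max_depth),
                 min_samples_split = as.integer(min_samples_split),
                 min_samples_leaf = as.integer(min_samples_leaf),
                 split_criterion = split_criterion,
                 seed = as.integer(seed)),
            class = "tree_hyperparams")
}

#' Load a run configuration from a YAML file
#'
#' Keys absent from the file take the pipeline defaults (see [run_config()]).
#' Unknown keys and out-of-range values are errors, so typos cannot silently
#' change an analysis. Tree hyperparameters may be given under a `tree:`
#' mapping.
#'
#' @param path Path to a YAML (or empty) config file.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config file must contain a key-value mapping",
                          call. = FALSE)
  known <- setdiff(names(formals(run_config)), "tree")
  unknown <- setdiff(names(raw), c(known, "tree"))
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  args <- raw[intersect(names(raw), known)]
  if (!is.null(raw$tree)) {
    tk <- names(formals(tree_hyperparams))
    tun <- setdiff(names(raw$tree), tk)
    if (length(tun)) {
      stop(sprintf("unknown tree config key(s): %s", paste(tun, collapse = ", ")),
           call. = FALSE)
    }
    args$tree <- do.call(tree_hyperparams, raw$tree)
  }
  do.call(run_config, args)
}
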