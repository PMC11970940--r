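#' Run the windowed PPG-to-stress pipeline over a recording
#'
#' For every analysis window (default 30 s, recomputed every 30 s):
#' high-pass filter, normalize to [-1, 1], detect systolic peaks (threshold
#' 0.5), derive RR intervals, extract the 34 HRV parameters, and apply the
#' stress model. Windows that fail anywhere (flatline, too few beats) are
#' carried through with `valid = FALSE` and never abort the session.
#'
#' @param rec A [ppg_record()].
#' @param model A trained `stress_model`, or NULL to compute features only.
#' @param cfg A [run_config()].
#' @return Data frame with one row per window: `start_s`, `valid`, `n_beats`,
#'   `label` (NA when invalid or `model` is NULL) and the 34 feature columns
#'   (NA when invalid).
#' @export
run_pipeline <- function(rec, model = NULL, cfg = run_config()) {
  stopifnot(inherits(rec, "ppg_record"))
  if (!is.null(model)) {
    stopifnot(inherits(model, "stress_model"))
    if (!identical(model$feature_order, hrv_feature_names())) {
      stop("model feature order does not match the canonical 34 features",
           call. = FALSE)
    }
  }
  wins <- window_signal(rec, window_s = cfg$window_s, step_s = cfg$step_s,
                        cutoff_hz = cfg$cutoff_hz, order = cfg$filter_order)
  rows <- lapply(wins, function(w) {
    feats <- stats::setNames(rep(NA_real_, 34L), hrv_feature_names())
    label <- NA_integer_
    n_beats <- 0L
    valid <- FALSE
    if (w$valid) {
      beats <- detect_peaks(w, threshold = cfg$peak_threshold,
                            refractory_ms = cfg$refractory_ms)
      n_beats <- length(beats$peak_indices)
      rr <- peaks_to_rr(beats, w$fs)
      v <- tryCatch(extract_features(rr, cfg), error = function(e) NULL)
      if (!is.null(v) && isTRUE(attr(v, "valid"))) {
        feats <- unclass(v)
        valid <- TRUE
        if (!is.null(model)) {
          label <- as.integer(predict_stress(model, v))
        }
      }
    }
    cbind(data.frame(start_s = w$start_s, valid = valid, n_beats = n_beats,
                     label = label),
          as.data.frame(as.list(feats)))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Aggregate window stress labels into per-phase scores
#'
#' Each valid window is assigned to the phase containing its start time.
#' Per phase, the sum of window labels and the normalized score
#' (sum / n windows, in [0, 2]) are reported in protocol order. Windows
#' outside every phase are excluded with a warning.
#'
#' @param results Window results from [run_pipeline()] (with labels).
#' @param annotations A [phase_plan()] (or data frame with `name`, `start_s`,
#'   `end_s`).
#' @return Data frame: `phase`, `n_windows` (valid, labeled), `sum_score`,
#'   `normalized_score`.
#' @export
phase_scores <- function(results, annotations) {
  idx <- vapply(results$start_s, function(s) {
    hit <- which(s >= annotations$start_s & s < annotations$end_s)
    if (length(hit)) hit[1L] else NA_integer_
  }, integer(1))
  if (any(is.na(idx))) {
    warning(sprintf("%d window(s) outside all phases were excluded",
                    sum(is.na(idx))), call. = FALSE)
  }
  out <- lapply(seq_len(nrow(annotations)), function(i) {
    sub <- results[!is.na(idx) & idx == i & results$valid & !is.na(results$label), ]
    data.frame(phase = annotations$name[i],
               n_windows = nrow(sub),
               sum_score = if (nrow(sub)) sum(sub$label) else 0L,
               normalized_score = if (nrow(sub)) sum(sub$label) / nrow(sub) else NA_real_)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# named phase subsets for the five questionnaire regressions
phase_subset_names <- function(subset, phases) {
  subset <- match.arg(subset, c("all", "rest1", "stroop", "rest23", "relax"))
  switch(subset,
         all = phases,
         rest1 = "Rest 1",
         stroop = c("Stroop 1", "Stroop 2"),
         rest23 = c("Rest 2", "Rest 3"),
         relax = "Relax")
}

#' Regress protocol stress scores on questionnaire stress scores
#'
#' Correlates a per-subject DASS-21 stress score with the sum of
#' decision-tree phase scores over a chosen subset of phases: all phases,
#' the baseline (Rest 1), the Stroop phases, the recovery rests, or the
#' relaxation phase.
#'
#' @param dass Named numeric vector of DASS-21 stress scores (names =
#'   subject ids).
#' @param phase_scores_by_subject Named list (same subject ids) of
#'   [phase_scores()] data frames.
#' @param subset One of `"all"`, `"rest1"`, `"stroop"`, `"rest23"`,
#'   `"relax"`, or a character vector of phase names.
#' @return A `regression_report` of phase-score sums on DASS scores.
#' @export
dass_regression <- function(dass, phase_scores_by_subject, subset = "all") {
  ids <- names(dass)
  if (is.null(ids) || !setequal(ids, names(phase_scores_by_subject))) {
    stop("subject ids of 'dass' and 'phase_scores_by_subject' must match",
         call. = FALSE)
  }
  if (length(ids) < 3L) stop("need >= 3 subjects", call. = FALSE)
  all_phases <- phase_scores_by_subject[[ids[1L]]]$phase
  wanted <- if (length(subset) == 1L && subset %in%
                c("all", "rest1", "stroop", "rest23", "relax")) {
    phase_subset_names(subset, all_phases)
  } else subset
  missing <- setdiff(wanted, all_phases)
  if (length(missing)) {
    stop(sprintf("unknown phase(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  y <- vapply(ids, function(id) {
    ps <- phase_scores_by_subject[[id]]
    sum(ps$sum_score[ps$phase %in% wanted])
  }, numeric(1))
  linear_regression(as.numeric(dass), y)
}

#' Compare adjacent protocol phases with a paired test
#'
#' For each adjacent phase pair (Rest 1 vs Stroop 1, Stroop 1 vs Rest 2, ...)
#' runs a paired two-sided Wilcoxon signed-rank test (default; robust to the
#' skew typical of HRV parameters) or a paired t-test across subjects on any
#' per-phase value (an HRV parameter or the stress score). With fewer than 6
#' pairs the Wilcoxon test cannot reach p < 0.05; the exact small-sample
#' method is used and noted.
#'
#' @param phase_values Numeric matrix or data frame, subjects x phases
#'   (columns in protocol order, named).
#' @param test `"wilcoxon"` or `"t"`.
#' @param alpha Significance level used for flagging.
#' @param p_adjust Multiplicity correction passed to [stats::p.adjust()]
#'   (default `"none"`, matching the uncorrected per-pair convention;
#'   `"holm"` available).
#' @return Data frame: `pair`, `statistic`, `p`, `p_adj`, `significant`,
#'   `method`.
#' @export
phase_comparison <- function(phase_values, test = c("wilcoxon", "t"),
                             alpha = 0.05, p_adjust = "none") {
  test <- match.arg(test)
  pv <- as.matrix(phase_values)
  if (nrow(pv) < 2L) stop("need >= 2 subjects", call. = FALSE)
  phases <- colnames(pv)
  if (is.null(phases)) phases <- paste0("phase", seq_len(ncol(pv)))
  out <- lapply(seq_len(ncol(pv) - 1L), function(i) {
    a <- pv[, i]; b <- pv[, i + 1L]
    if (test == "wilcoxon") {
      if (all(a == b)) {
        res <- list(statistic = NA_real_, p.value = 1, method = "wilcoxon (identical)")
      } else {
        wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                                  exact = NULL))
        res <- list(statistic = unname(wt$statistic), p.value = wt$p.value,
                    method = if (nrow(pv) < 6L) "wilcoxon (exact, small n)"
                             else "wilcoxon")
      }
    } else {
      tt <- stats::t.test(a, b, paired = TRUE)
      res <- list(statistic = unname(tt$statistic), p.value = tt$p.value,
                  method = "paired t")
    }
    data.frame(pair = paste(phases[i], "vs", phases[i + 1L]),
               statistic = res$statistic, p = res$p.value,
               method = res$method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  out$p_adj <- stats::p.adjust(out$p, method = p_adjust)
  out$significant <- out$p_adj < alpha
  out[, c("pair", "statistic", "p", "p_adj", "significant", "method")]
}
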