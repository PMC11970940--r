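#' Read a PPG recording from CSV
#'
#' Accepts either a single amplitude column (sampling rate supplied via `fs`)
#' or two columns, time in seconds followed by amplitude, in which case the
#' sampling rate is inferred from the median sample spacing. Inferred grids
#' are checked for jitter: any spacing deviating from the median by more than
#' `jitter_tol` (relative) is a format error.
#'
#' @param path Path to the CSV file. A header row is detected automatically.
#' @param fs Sampling rate in Hz; required for one-column files, optional
#'   (checked against the time column) for two-column files.
#' @param jitter_tol Maximum relative deviation of sample spacing from the
#'   median before the file is rejected as irregularly sampled.
#' @return A [ppg_record()].
#' @export
read_ppg_csv <- function(path, fs = NULL, jitter_tol = 0.01) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty PPG file", call. = FALSE)
  first <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  body <- if (has_header) lines[-1L] else lines
  if (!length(body)) stop("PPG file has a header but no data rows", call. = FALSE)
  fields <- strsplit(body, ",", fixed = TRUE)
  ncol <- length(fields[[1L]])
  if (!ncol %in% 1:2) {
    stop("PPG CSV must have one (amplitude) or two (time, amplitude) columns",
         call. = FALSE)
  }
  mat <- matrix(suppressWarnings(as.numeric(unlist(fields))),
                ncol = ncol, byrow = TRUE)
  bad <- which(apply(mat, 1L, function(r) any(!is.finite(r))))
  if (length(bad)) {
    stop(sprintf("non-numeric or non-finite value at data row %d of %s",
                 bad[1L], path), call. = FALSE)
  }
  if (ncol == 1L) {
    if (is.null(fs)) stop("'fs' is required for a one-column PPG file",
                          call. = FALSE)
    return(ppg_record(mat[, 1L], fs = fs))
  }
  tt <- mat[, 1L]
  dt <- diff(tt)
  if (any(dt <= 0)) stop("time column must be strictly increasing", call. = FALSE)
  med <- stats::median(dt)
  if (any(abs(dt - med) > jitter_tol * med)) {
    stop(sprintf("irregular sampling: spacing jitter exceeds %.1f%% of the median",
                 100 * jitter_tol), call. = FALSE)
  }
  fs_inf <- 1 / med
  if (!is.null(fs) && abs(fs_inf - fs) > jitter_tol * fs) {
    stop(sprintf("supplied fs = %g Hz disagrees with inferred %g Hz", fs, fs_inf),
         call. = FALSE)
  }
  ppg_record(mat[, 2L], fs = fs_inf, t0 = tt[1L])
}

#' Write a PPG recording to CSV
#'
#' @param rec A [ppg_record()].
#' @param path Output path.
#' @param time_column Write a leading time column in seconds (default TRUE).
#' @return `path`, invisibly.
#' @export
write_ppg_csv <- function(rec, path, time_column = TRUE) {
  stopifnot(inherits(rec, "ppg_record"))
  if (time_column) {
    tt <- rec$t0 + (seq_along(rec$samples) - 1L) / rec$fs
    df <- data.frame(time_s = tt, amplitude = rec$samples)
  } else {
    df <- data.frame(amplitude = rec$samples)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write RR-interval series as CSV
#'
#' The RR CSV convention is one interval per line in milliseconds, with a
#' `rr_ms` header.
#'
#' @param path File path.
#' @return `read_rr_csv`: an [rr_series()]; `write_rr_csv`: `path`, invisibly.
#' @export
read_rr_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path)
  if (!"rr_ms" %in% names(df)) {
    stop("RR CSV must contain an 'rr_ms' column", call. = FALSE)
  }
  if (any(!is.finite(df$rr_ms))) {
    stop(sprintf("non-finite RR value at data row %d",
                 which(!is.finite(df$rr_ms))[1L]), call. = FALSE)
  }
  rr_series(df$rr_ms)
}

#' @rdname read_rr_csv
#' @param rr An [rr_series()].
#' @export
write_rr_csv <- function(rr, path) {
  stopifnot(inherits(rr, "rr_series"))
  utils::write.csv(data.frame(rr_ms = rr$rr_ms), path, row.names = FALSE)
  invisible(path)
}

#' Validate an HRV feature table
#'
#' A feature table is a data frame with exactly the 34 canonical HRV columns
#' (see [hrv_feature_names()]), in order, plus an optional integer `label`
#' column with values in {0, 1, 2}.
#'
#' @param table A data frame.
#' @return The table, invisibly, or an error describing the schema violation.
#' @export
validate_feature_table <- function(table) {
  canon <- hrv_feature_names()
  have <- setdiff(names(table), "label")
  missing <- setdiff(canon, have)
  extra <- setdiff(have, canon)
  if (length(missing) || length(extra)) {
    msg <- c(if (length(missing))
               sprintf("missing feature column(s): %s", paste(missing, collapse = ", ")),
             if (length(extra))
               sprintf("unexpected column(s): %s", paste(extra, collapse = ", ")))
    stop(paste(msg, collapse = "; "), call. = FALSE)
  }
  if ("label" %in% names(table)) {
    lab <- table$label
    if (any(!lab %in% c(0L, 1L, 2L))) {
      stop("labels must be 0, 1 or 2", call. = FALSE)
    }
  }
  invisible(table)
}

#' Read / write HRV feature tables as CSV
#'
#' Feature CSVs carry the 34 canonical headers in order plus an optional
#' trailing `label` column. Values round-trip exactly (written at full
#' precision).
#'
#' @param path File path.
#' @return `read_feature_csv`: a validated data frame; `write_feature_csv`:
#'   `path`, invisibly.
#' @export
read_feature_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path)
  validate_feature_table(df)
  df[, c(hrv_feature_names(), intersect("label", names(df))), drop = FALSE]
}

#' @rdname read_feature_csv
#' @param table A feature-table data frame.
#' @export
write_feature_csv <- function(table, path) {
  validate_feature_table(table)
  cols <- c(hrv_feature_names(), intersect("label", names(table)))
  df <- table[, cols, drop = FALSE]
  # full-precision text so that read(write(x)) == x
  out <- vapply(df, function(col) format(col, digits = 17, scientific = TRUE,
                                         trim = TRUE), character(nrow(df)))
  if (nrow(df) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(NULL, cols))
  writeLines(c(paste(cols, collapse = ","),
               apply(out, 1L, paste, collapse = ",")), path)
  invisible(path)
}
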