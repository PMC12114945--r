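#' Construct a single-channel sEMG signal
#'
#' The basic container used throughout the package: a uniformly sampled
#' amplitude series together with its sampling rate and the time of the first
#' sample. Amplitude units are arbitrary (typically mV) and are never
#' interpreted by the detectors; every method in the package is either
#' scale-free by construction or normalizes its own decision statistic.
#'
#' @param samples Numeric vector of amplitudes; at least 2 finite values.
#' @param fs Sampling rate in Hz; must be positive.
#' @param t0 Time of the first sample in seconds (default 0).
#' @return An object of class `emg_signal` with fields `samples`, `fs`, `t0`.
#' @examples
#' x <- emg_signal(sin(2 * pi * 50 * seq(0, 1, by = 1 / 1500)), fs = 1500)
#' emg_duration(x)
#' @export
emg_signal <- function(samples, fs, t0 = 0) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)")
  if (length(samples) < 2L)
    stop("an emg_signal needs at least 2 samples")
  if (!all(is.finite(samples)))
    stop("all samples must be finite")
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0))
    stop("`t0` must be a single finite number (s)")
  structure(list(samples = samples, fs = fs, t0 = t0), class = "emg_signal")
}

#' Signal duration in seconds
#'
#' Duration spanned by the samples, `(n - 1) / fs`.
#'
#' @param x An `emg_signal`.
#' @return Duration in seconds.
#' @export
emg_duration <- function(x) {
  stopifnot(inherits(x, "emg_signal"))
  (length(x$samples) - 1L) / x$fs
}

#' Sample times of a signal
#'
#' @param x An `emg_signal`.
#' @return Numeric vector `t0 + (0:(n-1)) / fs`.
#' @export
emg_times <- function(x) {
  stopifnot(inherits(x, "emg_signal"))
  x$t0 + (seq_along(x$samples) - 1L) / x$fs
}

#' @export
print.emg_signal <- function(x, ...) {
  cat(sprintf(
    "<emg_signal> %d samples @ %g Hz, t0 = %g s, duration = %.4f s\n",
    length(x$samples), x$fs, x$t0, emg_duration(x)
  ))
  invisible(x)
}

# Guess the field separator of a delimited text file from its first line.
.guess_sep <- function(line) {
  if (grepl(",", line, fixed = TRUE)) "," else if (grepl("\t", line, fixed = TRUE)) "\t" else ""
}

#' Read an sEMG time series from delimited text
#'
#' Reads a comma- or tab-delimited file holding either a single amplitude
#' column or a time column plus an amplitude column. A single header row is
#' auto-detected (non-numeric first row) and skipped. When a time column is
#' present the sampling rate is inferred from the median time step and
#' cross-checked against `fs` when both are available.
#'
#' @param path Path to the file.
#' @param fs Sampling rate in Hz. Required when the file has no time column;
#'   otherwise optional (a discrepancy of more than 1% between `fs` and the
#'   inferred rate triggers a warning).
#' @param column Amplitude column, by name or 1-based index. Defaults to the
#'   only column of a one-column file, or the second column of a two-column
#'   file (the first being taken as time).
#' @param time_column Time column, by name or 1-based index, or `NA` to force
#'   "no time column". Defaults to column 1 when the file has two or more
#'   columns and `column` was not given.
#' @return An `emg_signal`. With a time column, `t0` is the first time value;
#'   otherwise `t0 = 0`.
#' @details Time steps with more than 5% jitter around the median step are
#'   rejected: the container assumes uniform sampling.
#' @export
read_emg_signal <- function(path, fs = NULL, column = NULL, time_column = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty file: ", path)
  sep <- .guess_sep(first)
  probe <- utils::read.table(path, sep = sep, header = FALSE, nrows = 1L,
                             stringsAsFactors = FALSE)
  has_header <- !all(vapply(probe, function(v)
    !is.na(suppressWarnings(as.numeric(as.character(v)))), logical(1)))
  df <- utils::read.table(path, sep = sep, header = has_header,
                          stringsAsFactors = FALSE)
  if (nrow(df) < 2L) stop("need at least 2 data rows, got ", nrow(df))

  resolve <- function(col) {
    if (is.character(col)) {
      j <- match(col, names(df))
      if (is.na(j)) stop("no such column: ", col)
      j
    } else as.integer(col)
  }
  if (is.null(time_column)) {
    time_column <- if (is.null(column) && ncol(df) >= 2L) 1L else NA_integer_
  } else if (!is.na(time_column)) time_column <- resolve(time_column)
  if (is.null(column)) {
    column <- if (!is.na(time_column) && ncol(df) >= 2L) {
      setdiff(seq_len(ncol(df)), time_column)[1L]
    } else 1L
  } else column <- resolve(column)

  amp <- suppressWarnings(as.numeric(df[[column]]))
  if (anyNA(amp)) stop("non-numeric values in amplitude column")

  t0 <- 0
  if (!is.na(time_column)) {
    tt <- suppressWarnings(as.numeric(df[[time_column]]))
    if (anyNA(tt)) stop("non-numeric values in time column")
    dt <- diff(tt)
    med <- stats::median(dt)
    if (med <= 0) stop("time column must be strictly increasing")
    if (any(abs(dt - med) > 0.05 * med))
      stop("inconsistent time step (>5% jitter); signal must be uniformly sampled")
    fs_inferred <- 1 / med
    if (!is.null(fs) && abs(fs_inferred - fs) > 0.01 * fs)
      warning(sprintf("given fs = %g Hz disagrees with inferred %g Hz by >1%%",
                      fs, fs_inferred))
    if (is.null(fs)) fs <- fs_inferred
    t0 <- tt[1L]
  }
  if (is.null(fs)) stop("`fs` is required when the file has no time column")
  emg_signal(amp, fs = fs, t0 = t0)
}

#' Construct an onset detection result
#'
#' @param method Detector identifier (e.g. `"mse"`, `"threshold"`).
#' @param k_star 1-based detected window index, or `NA` when no onset is
#'   declared.
#' @param t_star Onset time in seconds, or `NA`. Must be present exactly when
#'   `k_star` is present.
#' @param diagnostics Named list of per-method intermediate series (entropy
#'   trend, threshold level, ...). Not serialized by [write_onset_results()].
#' @param params Named list of scalar parameters used by the detector.
#' @return An object of class `onset_result`.
#' @export
onset_result <- function(method, k_star = NA, t_star = NA,
                         diagnostics = list(), params = list()) {
  if (is.na(k_star) != is.na(t_star))
    stop("k_star and t_star must be both present or both absent")
  structure(list(
    method = as.character(method),
    k_star = if (is.na(k_star)) NA_integer_ else as.integer(k_star),
    t_star = if (is.na(t_star)) NA_real_ else as.numeric(t_star),
    diagnostics = diagnostics,
    params = params
  ), class = "onset_result")
}

#' @export
print.onset_result <- function(x, ...) {
  if (is.na(x$t_star)) {
    cat(sprintf("<onset_result> method = %s: no onset declared\n", x$method))
  } else {
    cat(sprintf("<onset_result> method = %s: t* = %.4f s (window k* = %d)\n",
                x$method, x$t_star, x$k_star))
  }
  invisible(x)
}

.pack_params <- function(p) {
  if (length(p) == 0L) return("")
  keep <- vapply(p, function(v) is.atomic(v) && length(v) == 1L, logical(1))
  p <- p[keep]
  paste(sprintf("%s=%s", names(p), vapply(p, format, character(1), digits = 17)),
        collapse = ";")
}

.unpack_params <- function(s) {
  if (is.na(s) || !nzchar(s)) return(list())
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], "=", fixed = TRUE)
  out <- lapply(kv, function(x) {
    v <- x[2L]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(out) <- vapply(kv, `[`, character(1), 1L)
  out
}

#' Write onset results to a delimited file
#'
#' Serializes one or more [onset_result()] objects as tab-delimited text with
#' one header row and columns `method`, `k_star`, `t_star`, `params`. Absent
#' onsets are written as `NA` fields. Scalar parameters round-trip through
#' [read_onset_results()]; diagnostics series are not serialized.
#'
#' @param results An `onset_result` or a list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_onset_results <- function(results, path) {
  if (inherits(results, "onset_result")) results <- list(results)
  df <- data.frame(
    method = vapply(results, `[[`, character(1), "method"),
    k_star = vapply(results, `[[`, integer(1), "k_star"),
    t_star = vapply(results, `[[`, numeric(1), "t_star"),
    params = vapply(results, function(r) .pack_params(r$params), character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read onset results written by [write_onset_results()]
#'
#' @param path Path to the file.
#' @return A list of `onset_result` objects, in file order.
#' @export
read_onset_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "numeric", "character"),
                          na.strings = "NA")
  if (!"params" %in% names(df)) df$params <- ""
  lapply(seq_len(nrow(df)), function(i) {
    onset_result(df$method[i], df$k_star[i], df$t_star[i],
                 params = .unpack_params(df$params[i]))
  })
}
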