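#' Default parameter set for the detection pipeline
#'
#' Returns the nested list of parameters that every detector and the
#' synthetic generator consume. Values can be overridden via `...` using
#' flat dotted keys, e.g. `emg_params(window.length_ms = 96)`, or loaded from
#' a flat key-value text file with [read_emg_config()].
#'
#' @section Defaults:
#' * `filter.low_hz = 20`, `filter.high_hz = 450`, `filter.order = 5`,
#'   `filter.enabled = TRUE` — zero-phase Butterworth band-pass applied
#'   before any detector.
#' * `window.length_ms = 128`, `window.overlap = 0.5`, `window.zscore = TRUE`
#'   — sliding analysis windows; each window is z-scored independently.
#' * `emd.max_imfs = 6`, `emd.sd_tol = 0.2`, `emd.max_sift_iters = 100` —
#'   sifting depth and Cauchy stopping tolerance.
#' * `hht.n_bins = 45`, `hht.f_max_hz = 450`, `hht.edge_exclude = 0.05`,
#'   `hht.power_spectrum = FALSE` — marginal-spectrum binning (equal width,
#'   10 Hz resolution over the pass band by default).
#' * `detector.mode = "mse"`, `detector.smooth_len = 5`,
#'   `detector.reject_delta = 0` — trend smoothing length (windows; odd) and
#'   the optional no-activation rejection threshold (0 = always detect).
#' * `baseline.threshold_frac = 0.30`, `baseline.tke_j = 8`,
#'   `baseline.baseline_ms = 300`, `baseline.consec = 2`,
#'   `baseline.wavelet = "db4"`, `baseline.levels = 4` — comparison
#'   detectors.
#' * `evaluate.tolerance_s = 0.2`, `evaluate.reference = "threshold"`,
#'   `evaluate.truth_ref = "start"` — benchmark scoring conventions.
#'
#' @param ... Flat dotted-key overrides.
#' @return A nested named list.
#' @export
emg_params <- function(...) {
  p <- list(
    filter = list(low_hz = 20, high_hz = 450, order = 5L, enabled = TRUE),
    window = list(length_ms = 128, overlap = 0.5, zscore = TRUE),
    emd = list(max_imfs = 6L, sd_tol = 0.2, max_sift_iters = 100L),
    hht = list(n_bins = 45L, f_max_hz = 450, edge_exclude = 0.05,
               power_spectrum = FALSE),
    detector = list(mode = "mse", smooth_len = 5L, reject_delta = 0),
    baseline = list(threshold_frac = 0.30, tke_j = 8, baseline_ms = 300,
                    consec = 2L, wavelet = "db4", levels = 4L),
    evaluate = list(tolerance_s = 0.2, reference = "threshold",
                    truth_ref = "start")
  )
  set_emg_params(p, list(...))
}

#' Apply flat dotted-key overrides to a parameter list
#'
#' @param params A nested parameter list as from [emg_params()].
#' @param overrides Named list with dotted keys (`"filter.low_hz"`, ...).
#' @return The updated parameter list.
#' @export
set_emg_params <- function(params, overrides) {
  for (key in names(overrides)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
      stop("parameter keys must be of the form section.name, got: ", key)
    sec <- parts[1L]; nm <- parts[2L]
    if (is.null(params[[sec]]) || is.null(params[[sec]][[nm]]))
      stop("unknown parameter: ", key)
    template <- params[[sec]][[nm]]
    value <- overrides[[key]]
    if (is.numeric(template) && is.character(value))
      value <- as.numeric(value)
    if (is.logical(template) && is.character(value))
      value <- as.logical(toupper(value))
    if (is.integer(template)) value <- as.integer(value)
    params[[sec]][[nm]] <- value
  }
  params
}

#' Read a flat key-value configuration file
#'
#' The file holds one `section.name = value` (or `section.name: value`) pair
#' per line; blank lines and lines starting with `#` are ignored. Values are
#' coerced to the type of the corresponding default.
#'
#' @param path Path to the configuration file.
#' @param params Base parameter list to override (default [emg_params()]).
#' @return The merged parameter list.
#' @export
read_emg_config <- function(path, params = emg_params()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  overrides <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_.]+)\\s*[:=]\\s*(.*)$", ln))[[1L]]
    if (length(m) != 3L) stop("cannot parse config line: ", ln)
    overrides[[m[2L]]] <- trimws(m[3L])
  }
  set_emg_params(params, overrides)
}
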