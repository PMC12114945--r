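#' Per-window marginal-spectrum-entropy sequence
#'
#' Runs the EMD / Hilbert-spectrum / entropy pipeline on every sliding
#' window of a signal and collects the normalized entropy values
#' `M = [MSE_1, ..., MSE_K]`. Windows are z-scored independently before
#' decomposition when `params$window$zscore` is `TRUE` (entropy itself is
#' scale-free, so this only stabilizes the numerics). A window with no
#' usable spectrum (e.g. near-constant) inherits the previous window's
#' value; a failing first window falls back to 1 (maximal uncertainty).
#'
#' @param x An `emg_signal` (already filtered, if filtering is wanted).
#' @param plan A `window_plan` for `x` (default: plan from `params`).
#' @param params Parameter list from [emg_params()].
#' @return An object of class `entropy_trend` with `M`, `T` (`NULL` until
#'   [smooth_trend()] is applied), `plan`, `smooth_len` (`NA`), and
#'   `n_failed` (number of carried windows).
#' @export
entropy_sequence <- function(x, plan = NULL, params = emg_params()) {
  stopifnot(inherits(x, "emg_signal"))
  if (is.null(plan))
    plan <- plan_windows(x, params$window$length_ms, params$window$overlap)
  M <- numeric(plan$K)
  failed <- 0L
  for (k in seq_len(plan$K)) {
    w <- .window_at(x$samples, plan, k)
    if (isTRUE(params$window$zscore)) w <- zscore_window(w)
    spec <- .window_spectrum(w, x$fs, params)
    val <- if (is.null(spec)) NA_real_ else compute_mse(spec)$value
    if (is.na(val)) {
      failed <- failed + 1L
      val <- if (k == 1L) 1 else M[k - 1L]
    }
    M[k] <- val
  }
  if (failed > plan$K / 2)
    stop("more than half of the windows produced no usable spectrum; ",
         "input looks unusable for entropy tracking")
  structure(list(M = M, T = NULL, plan = plan, smooth_len = NA_integer_,
                 n_failed = failed),
            class = "entropy_trend")
}

#' Centered moving-average smoothing of an entropy sequence
#'
#' Applies a centered moving average of odd length, truncated at the edges
#' (shorter averages near the boundaries), so the output has the same
#' length as the input and constants are preserved.
#'
#' @param M Numeric vector (per-window entropy, or any per-window statistic).
#' @param smooth_len Odd integer window length in windows; `1` is the
#'   identity.
#' @return Smoothed vector of the same length.
#' @export
smooth_trend <- function(M, smooth_len = 5L) {
  K <- length(M)
  smooth_len <- as.integer(smooth_len)
  if (smooth_len < 1L || smooth_len > K)
    stop("smooth_len must be between 1 and length(M)")
  if (smooth_len %% 2L == 0L)
    stop("smooth_len must be odd (centering is undefined for even lengths)")
  half <- smooth_len %/% 2L
  cs <- c(0, cumsum(M))
  lo <- pmax(seq_len(K) - half, 1L)
  hi <- pmin(seq_len(K) + half, K)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Onset from the steepest drop of a trend sequence
#'
#' Computes the first-order difference `Delta_k = T_{k+1} - T_k` and places
#' the onset at the window where the slope is most negative,
#' `k* = argmin_k Delta_k` (earliest index on ties), mapping it to time as
#' `t* = t0 + (k* - 1) * s` with `s` the window step in seconds. An
#' optional rejection rule declares "no onset" when even the steepest drop
#' is shallower than `-reject_delta`; with the default `reject_delta = 0`
#' an onset is always returned.
#'
#' @param T Numeric trend sequence of length >= 2.
#' @param plan The `window_plan` that produced `T` (supplies `t0`, step, fs).
#' @param reject_delta Non-negative; 0 disables rejection.
#' @param method Label recorded in the result.
#' @return An [onset_result()]; diagnostics carry `trend` and `delta`.
#' @examples
#' pl <- structure(list(L_samples = 192L, s_samples = 96L, K = 5L,
#'                      t0 = 0, fs = 1500), class = "window_plan")
#' detect_onset(c(0.90, 0.88, 0.85, 0.60, 0.55), pl)  # k* = 3, t* = 0.128
#' @export
detect_onset <- function(T, plan, reject_delta = 0, method = "mse") {
  K <- length(T)
  if (K < 2L) stop("need at least 2 trend points")
  delta <- diff(T)
  k_star <- which.min(delta)  # earliest index on ties
  if (reject_delta > 0 && delta[k_star] > -reject_delta) {
    return(onset_result(method, diagnostics = list(trend = T, delta = delta)))
  }
  s_sec <- plan$s_samples / plan$fs
  onset_result(method, k_star = k_star,
               t_star = plan$t0 + (k_star - 1L) * s_sec,
               diagnostics = list(trend = T, delta = delta))
}

# Per-window mean squared amplitude (windows NOT z-scored: z-scoring would
# flatten the very quantity this ablation tracks).
.energy_sequence <- function(x, plan) {
  vapply(seq_len(plan$K), function(k) mean(.window_at(x$samples, plan, k)^2),
         numeric(1))
}

# Ablation without the sliding window: one global EMD, then normalized
# entropy of the marginal spectrum accumulated from the signal start up to
# each grid point (the grid reuses the window plan's time points so modes
# stay comparable).
.cumulative_entropy_sequence <- function(x, plan, params) {
  d <- emd(x$samples, max_imfs = params$emd$max_imfs,
           sd_tol = params$emd$sd_tol, max_iters = params$emd$max_sift_iters)
  if (length(d$imfs) == 0L) stop("global EMD produced no IMFs")
  attrs <- lapply(d$imfs, analytic_attrs, fs = x$fs,
                  edge_exclude = params$hht$edge_exclude)
  n_bins <- params$hht$n_bins
  width <- params$hht$f_max_hz / n_bins
  dt <- 1 / x$fs
  idx <- unlist(lapply(attrs, function(a) which(a$valid)))
  amp <- unlist(lapply(attrs, function(a) a$amplitude[a$valid]))
  freq <- unlist(lapply(attrs, function(a) a$frequency[a$valid]))
  if (length(idx) == 0L) stop("empty spectrum: no usable samples")
  w <- if (isTRUE(params$hht$power_spectrum)) amp^2 * dt else amp * dt
  bin <- pmin(floor(freq / width) + 1L, n_bins)
  ord <- order(idx)
  idx <- idx[ord]; w <- w[ord]; bin <- bin[ord]
  # grid g covers samples up to the end of what window g would span
  cut <- (seq_len(plan$K) - 1L) * plan$s_samples + plan$L_samples
  upto <- findInterval(cut, idx)
  M <- numeric(plan$K)
  h <- numeric(n_bins)
  prev <- 0L
  for (g in seq_len(plan$K)) {
    if (upto[g] > prev) {
      sl <- (prev + 1L):upto[g]
      acc <- rowsum(w[sl], bin[sl])
      ii <- as.integer(rownames(acc))
      h[ii] <- h[ii] + acc[, 1L]
      prev <- upto[g]
    }
    M[g] <- if (sum(h) > 0) compute_mse(h)$value else 1
  }
  M
}

#' Detect muscle activation onset
#'
#' The front door of the package. Mode `"mse"` is the full detector:
#' band-pass filter, sliding windows, per-window marginal-spectrum entropy,
#' moving-average trend, onset at the steepest trend drop. The remaining
#' modes are ablation variants used to quantify each module's contribution:
#'
#' * `"energy-slope"`: the entropy statistic is replaced by per-window mean
#'   squared amplitude (normalized by its maximum); activation raises
#'   energy, so the onset is placed at the steepest *rise* of the energy
#'   trend, with rejection when even the steepest rise is below
#'   `reject_delta`.
#' * `"mse-only"`: no slope analysis; the onset window is the global
#'   minimum of the smoothed entropy trend. Rejection triggers when the
#'   trend's total excursion `max(T) - min(T)` is below `reject_delta`.
#' * `"mse-nowindow"`: no sliding window; a single EMD of the whole signal
#'   feeds a cumulative-to-t marginal spectrum whose entropy is evaluated
#'   at coarse grid points, and the steepest drop of that (unsmoothed)
#'   sequence gives the onset.
#'
#' @param x An `emg_signal`.
#' @param mode One of `"mse"`, `"energy-slope"`, `"mse-only"`,
#'   `"mse-nowindow"`.
#' @param params Parameter list from [emg_params()]; `detector.reject_delta`
#'   (default 0) enables the no-activation guard, and `filter.enabled`
#'   controls the band-pass stage.
#' @return An [onset_result()] with the mode recorded; diagnostics include
#'   the entropy/energy sequence `M`, the smoothed trend, and the slope
#'   sequence.
#' @examples
#' \donttest{
#' gen <- generate_emg(synth_spec(duration = 5, t_on = 2, rise = 1, seed = 7))
#' detect(gen$signal, mode = "mse")
#' }
#' @export
detect <- function(x, mode = c("mse", "energy-slope", "mse-only", "mse-nowindow"),
                   params = emg_params()) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "emg_signal"))
  if (isTRUE(params$filter$enabled))
    x <- bandpass(x, params$filter$low_hz, params$filter$high_hz,
                  params$filter$order)
  plan <- plan_windows(x, params$window$length_ms, params$window$overlap)
  rd <- params$detector$reject_delta
  sl <- min(params$detector$smooth_len, if (plan$K %% 2L == 0L) plan$K - 1L else plan$K)

  if (mode == "energy-slope") {
    E <- .energy_sequence(x, plan)
    if (max(E) > 0) E <- E / max(E)
    Tr <- smooth_trend(E, sl)
    delta <- diff(Tr)
    k_star <- which.max(delta)
    res <- if (rd > 0 && delta[k_star] < rd) {
      onset_result(mode)
    } else {
      s_sec <- plan$s_samples / plan$fs
      onset_result(mode, k_star, plan$t0 + (k_star - 1L) * s_sec)
    }
    res$diagnostics <- list(M = E, trend = Tr, delta = delta)
    res$params <- list(smooth_len = sl, reject_delta = rd)
    return(res)
  }

  if (mode == "mse-nowindow") {
    M <- .cumulative_entropy_sequence(x, plan, params)
    res <- detect_onset(M, plan, reject_delta = rd, method = mode)
    res$diagnostics$M <- M
    res$params <- list(reject_delta = rd)
    return(res)
  }

  tr <- entropy_sequence(x, plan, params)
  Tr <- smooth_trend(tr$M, sl)
  if (mode == "mse-only") {
    k_star <- which.min(Tr)
    res <- if (rd > 0 && (max(Tr) - min(Tr)) < rd) {
      onset_result(mode)
    } else {
      s_sec <- plan$s_samples / plan$fs
      onset_result(mode, k_star, plan$t0 + (k_star - 1L) * s_sec)
    }
    res$diagnostics <- list(M = tr$M, trend = Tr)
    res$params <- list(smooth_len = sl, reject_delta = rd)
    return(res)
  }
  res <- detect_onset(Tr, plan, reject_delta = rd, method = mode)
  res$diagnostics$M <- tr$M
  res$params <- list(smooth_len = sl, reject_delta = rd)
  res
}
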