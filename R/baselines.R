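#' Parameters of the comparison detectors
#'
#' @param threshold_frac Fraction of the envelope maximum used by the
#'   relative amplitude threshold detector (default 0.30).
#' @param tke_j Baseline multiplier for the Teager-Kaiser energy threshold
#'   `mu_b + j * sigma_b` (default 8).
#' @param baseline_ms Duration of the quiescent reference segment at the
#'   start of the recording, in ms (default 300).
#' @param consec Consecutive supra-threshold windows (or 50 ms blocks for
#'   TKE) required to declare an onset (default 2).
#' @param wavelet Mother wavelet identifier; `"db4"` is the only built-in.
#' @param levels Wavelet decomposition depth (default 4).
#' @return A list of class `baseline_params`.
#' @export
baseline_params <- function(threshold_frac = 0.30, tke_j = 8,
                            baseline_ms = 300, consec = 2L,
                            wavelet = "db4", levels = 4L) {
  stopifnot(threshold_frac > 0, threshold_frac < 1, tke_j > 0,
            baseline_ms > 0, consec >= 1L, levels >= 1L)
  structure(list(threshold_frac = threshold_frac, tke_j = tke_j,
                 baseline_ms = baseline_ms, consec = as.integer(consec),
                 wavelet = wavelet, levels = as.integer(levels)),
            class = "baseline_params")
}

#' Relative amplitude threshold detector
#'
#' Rectifies the signal, extracts a linear envelope (2nd-order zero-phase
#' Butterworth low-pass at 10 Hz), and marks the onset at the first sample
#' where the envelope exceeds `threshold_frac` times its maximum. Because
#' the threshold is relative, the detection is invariant to amplitude
#' scaling; it also always fires on any non-constant signal, so this
#' detector has no rejection rule.
#'
#' @param x An `emg_signal` (non-constant).
#' @param params A [baseline_params()] list.
#' @return An [onset_result()] with method `"threshold"`.
#' @export
detect_threshold <- function(x, params = baseline_params()) {
  stopifnot(inherits(x, "emg_signal"))
  if (max(x$samples) == min(x$samples)) stop("constant signal: no threshold crossing")
  env <- .lowpass_zero_phase(abs(x$samples), x$fs, cutoff = 10, order = 2L)
  thr <- params$threshold_frac * max(env)
  idx <- which(env > thr)[1L]
  if (is.na(idx)) return(onset_result("threshold",
                                      diagnostics = list(envelope = env, level = thr)))
  onset_result("threshold", k_star = idx, t_star = x$t0 + (idx - 1L) / x$fs,
               diagnostics = list(envelope = env, level = thr),
               params = list(threshold_frac = params$threshold_frac))
}

#' Teager-Kaiser energy operator
#'
#' `Psi(i) = x(i)^2 - x(i-1) * x(i+1)` on interior samples; the endpoints
#' copy the nearest interior value so the output length equals the input
#' length. On a pure tone `A * cos(Omega * n)` the interior output is the
#' constant `A^2 * sin(Omega)^2`.
#'
#' @param x Numeric vector of length >= 3.
#' @return Energy vector of the same length.
#' @export
tke_operator <- function(x) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples")
  psi <- numeric(n)
  i <- 2L:(n - 1L)
  psi[i] <- x[i]^2 - x[i - 1L] * x[i + 1L]
  psi[1L] <- psi[2L]
  psi[n] <- psi[n - 1L]
  psi
}

# First index at which `ok` holds for `run_len` consecutive entries, or NA.
.first_run <- function(ok, run_len) {
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= run_len)
  if (length(hit) == 0L) NA_integer_ else starts[hit[1L]]
}

#' Teager-Kaiser energy onset detector
#'
#' Smooths the TKE profile with a centered 50 ms moving average, estimates
#' baseline statistics on the first `baseline_ms` of the recording (assumed
#' quiescent), and marks the onset at the first sample where the smoothed
#' energy stays above `mu_b + tke_j * sigma_b` for at least
#' `consec` x 50 ms. Returns an absent onset if the threshold is never held.
#'
#' @param x An `emg_signal` at least `baseline_ms` long.
#' @param params A [baseline_params()] list.
#' @return An [onset_result()] with method `"tke"`.
#' @export
detect_tke <- function(x, params = baseline_params()) {
  stopifnot(inherits(x, "emg_signal"))
  n <- length(x$samples)
  nb <- as.integer(round(params$baseline_ms / 1000 * x$fs))
  if (nb > n) stop("baseline window longer than the signal")
  psi <- tke_operator(x$samples)
  n50 <- max(1L, as.integer(round(0.05 * x$fs)))
  if (n50 %% 2L == 0L) n50 <- n50 + 1L
  psi_s <- smooth_trend(psi, min(n50, if (n %% 2L == 0L) n - 1L else n))
  mu <- mean(psi_s[seq_len(nb)])
  sd_b <- stats::sd(psi_s[seq_len(nb)])
  thr <- mu + params$tke_j * sd_b
  run <- params$consec * max(1L, as.integer(round(0.05 * x$fs)))
  idx <- .first_run(psi_s > thr, run)
  if (is.na(idx))
    return(onset_result("tke", diagnostics = list(energy = psi_s, level = thr)))
  onset_result("tke", k_star = idx, t_star = x$t0 + (idx - 1L) / x$fs,
               diagnostics = list(energy = psi_s, level = thr),
               params = list(tke_j = params$tke_j,
                             baseline_ms = params$baseline_ms))
}

#' RMS windowing onset detector
#'
#' Computes per-window RMS amplitude, a baseline threshold
#' `mu_b + 3 * sigma_b` from the first `baseline_ms / step` windows, and
#' marks the onset at the left edge of the first run of at least `consec`
#' consecutive supra-threshold windows.
#'
#' @param x An `emg_signal`.
#' @param params A [baseline_params()] list.
#' @param plan A `window_plan`; defaults to the package's standard plan.
#' @return An [onset_result()] with method `"rms"`.
#' @export
detect_rms <- function(x, params = baseline_params(), plan = NULL) {
  stopifnot(inherits(x, "emg_signal"))
  if (is.null(plan)) plan <- plan_windows(x)
  rms <- vapply(seq_len(plan$K),
                function(k) sqrt(mean(.window_at(x$samples, plan, k)^2)),
                numeric(1))
  s_sec <- plan$s_samples / plan$fs
  B <- as.integer(floor(params$baseline_ms / 1000 / s_sec))
  if (B < 2L) stop("fewer than 2 baseline windows; increase baseline_ms")
  B <- min(B, plan$K)
  thr <- mean(rms[seq_len(B)]) + 3 * stats::sd(rms[seq_len(B)])
  k <- .first_run(rms > thr, params$consec)
  if (is.na(k))
    return(onset_result("rms", diagnostics = list(rms = rms, level = thr)))
  onset_result("rms", k_star = k, t_star = plan$t0 + (k - 1L) * s_sec,
               diagnostics = list(rms = rms, level = thr),
               params = list(consec = params$consec))
}

# Daubechies-4 (four vanishing moments, length-8) decomposition filters.
.db4_lowpass <- c(
  0.230377813308855230, 0.714846570552541500, 0.630880767929590400,
  -0.027983769416983850, -0.187034811718881140, 0.030841381835986965,
  0.032883011666982945, -0.010597401784997278
)

# One level of periodic convolution-decimation.
.conv_dec <- function(x, f) {
  n <- length(x)
  L <- length(f)
  xp <- c(x, rep_len(x, L - 1L))
  y <- numeric(n)
  for (j in seq_len(L)) y <- y + f[j] * xp[seq_len(n) + j - 1L]
  y[seq.int(1L, n, by = 2L)]
}

#' Multi-level discrete wavelet detail decomposition
#'
#' Periodic DWT (Mallat pyramid) returning the detail coefficients of each
#' level together with the approximate time support of each coefficient in
#' samples of the original signal. Only the db4 mother wavelet is built in.
#'
#' @param x Numeric vector, length >= `2^levels`.
#' @param levels Decomposition depth.
#' @param wavelet Mother wavelet id (only `"db4"`).
#' @return A list with one element per level: `coef` (detail coefficients),
#'   `support_start` and `support_len` (samples).
#' @export
dwt_details <- function(x, levels = 4L, wavelet = "db4") {
  if (wavelet != "db4") stop("only the db4 wavelet is built in")
  if (length(x) < 2^levels) stop("signal too short for ", levels, " levels")
  h <- .db4_lowpass
  g <- rev(h) * (-1)^(seq_along(h) - 1L)  # quadrature mirror high-pass
  out <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    d <- .conv_dec(a, g)
    a <- .conv_dec(a, h)
    step <- 2^j
    out[[j]] <- list(
      coef = d,
      support_start = (seq_along(d) - 1L) * step + 1L,
      support_len = step * (length(h) - 1L)
    )
  }
  out
}

#' Wavelet energy redistribution onset detector
#'
#' Decomposes the signal with a multi-level periodic DWT (db4 by default),
#' assigns each squared detail coefficient to every analysis window its
#' support intersects, and applies the same `mu_b + 3 * sigma_b`
#' persistence rule as [detect_rms()] to the per-window detail energy.
#'
#' @param x An `emg_signal` of length >= `2^levels`.
#' @param params A [baseline_params()] list.
#' @param plan A `window_plan`; defaults to the package's standard plan.
#' @return An [onset_result()] with method `"wavelet"`.
#' @export
detect_wavelet <- function(x, params = baseline_params(), plan = NULL) {
  stopifnot(inherits(x, "emg_signal"))
  if (is.null(plan)) plan <- plan_windows(x)
  dec <- dwt_details(x$samples, levels = params$levels, wavelet = params$wavelet)
  energy <- numeric(plan$K)
  win_start <- (seq_len(plan$K) - 1L) * plan$s_samples + 1L
  win_end <- win_start + plan$L_samples - 1L
  for (lev in dec) {
    c_start <- lev$support_start
    c_end <- c_start + lev$support_len - 1L
    sq <- lev$coef^2
    # window k gets coefficients with c_start <= win_end[k] & c_end >= win_start[k]
    for (k in seq_len(plan$K)) {
      sel <- c_start <= win_end[k] & c_end >= win_start[k]
      energy[k] <- energy[k] + sum(sq[sel])
    }
  }
  s_sec <- plan$s_samples / plan$fs
  B <- as.integer(floor(params$baseline_ms / 1000 / s_sec))
  if (B < 2L) stop("fewer than 2 baseline windows; increase baseline_ms")
  B <- min(B, plan$K)
  # tiny absolute floor so numerically flat energy sequences never trigger
  thr <- mean(energy[seq_len(B)]) + 3 * stats::sd(energy[seq_len(B)]) +
    1e-12 * max(energy)
  k <- .first_run(energy > thr, params$consec)
  if (is.na(k))
    return(onset_result("wavelet", diagnostics = list(energy = energy, level = thr)))
  onset_result("wavelet", k_star = k, t_star = plan$t0 + (k - 1L) * s_sec,
               diagnostics = list(energy = energy, level = thr),
               params = list(levels = params$levels))
}
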