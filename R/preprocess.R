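# Zero-phase IIR filtering with odd-reflection end padding.
# Forward-backward application squares the magnitude response and cancels
# phase, so a 5th-order design acts as an effective 10th-order filter with
# no group delay. Padding length follows the usual 3 x (filter length) rule.
.filtfilt_refl <- function(b, a, x) {
  npad <- 3L * (max(length(a), length(b)) - 1L) * 2L + 3L
  n <- length(x)
  if (npad >= n)
    stop("signal too short for stable two-pass filtering (need > ",
         npad, " samples)")
  head_pad <- 2 * x[1L] - x[(npad + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - npad)]
  xp <- c(head_pad, x, tail_pad)
  y <- as.numeric(signal::filter(b, a, xp))
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  y[(npad + 1L):(npad + n)]
}

#' Band-pass filter an sEMG signal (zero phase)
#'
#' Applies a Butterworth band-pass forward and backward so that pass-band
#' components keep their timing exactly (no group delay). The default
#' 20-450 Hz band removes motion artifact and low-frequency drift below the
#' EMG band and wideband noise above it.
#'
#' @param x An `emg_signal`.
#' @param low,high Band edges in Hz; `0 < low < high < fs/2`.
#' @param order Butterworth prototype order (default 5). The two-pass
#'   application makes the effective order twice this.
#' @return A filtered `emg_signal` of the same length, fs and t0.
#' @export
bandpass <- function(x, low = 20, high = 450, order = 5L) {
  stopifnot(inherits(x, "emg_signal"))
  if (!(low > 0 && high > low)) stop("need 0 < low < high")
  if (high >= x$fs / 2) stop("high cutoff must be below the Nyquist frequency")
  if (order < 1L) stop("order must be >= 1")
  bf <- signal::butter(order, c(low, high) / (x$fs / 2), type = "pass")
  emg_signal(.filtfilt_refl(bf$b, bf$a, x$samples), fs = x$fs, t0 = x$t0)
}

# Low-pass companion used by the linear-envelope baseline detector.
.lowpass_zero_phase <- function(samples, fs, cutoff, order = 2L) {
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  .filtfilt_refl(bf$b, bf$a, samples)
}

#' Plan sliding analysis windows
#'
#' Converts a window length in milliseconds and an overlap fraction into a
#' sample-domain plan: window length `L_samples`, step `s_samples`, and the
#' number of complete windows `K`. Trailing samples that do not fill a
#' window are dropped. Window `k` (1-based) starts at sample
#' `(k - 1) * s_samples + 1`, i.e. at time `t0 + (k - 1) * s_samples / fs`.
#'
#' @param x An `emg_signal`.
#' @param length_ms Window length in milliseconds (default 128).
#' @param overlap Overlap fraction in `[0, 1)` (default 0.5).
#' @return An object of class `window_plan` with fields `L_samples`,
#'   `s_samples`, `K`, `t0`, `fs`.
#' @examples
#' x <- emg_signal(rnorm(1500), fs = 1500)
#' plan_windows(x)  # L = 192 samples, s = 96, K = 14
#' @export
plan_windows <- function(x, length_ms = 128, overlap = 0.5) {
  stopifnot(inherits(x, "emg_signal"))
  if (!(overlap >= 0 && overlap < 1)) stop("overlap must be in [0, 1)")
  L <- as.integer(round(length_ms * x$fs / 1000))
  if (L < 2L) stop("window length converts to fewer than 2 samples")
  n <- length(x$samples)
  if (n < L) stop("signal shorter than one window")
  s <- max(1L, as.integer(round(L * (1 - overlap))))
  K <- (n - L) %/% s + 1L
  structure(list(L_samples = L, s_samples = s, K = K, t0 = x$t0, fs = x$fs),
            class = "window_plan")
}

#' @export
print.window_plan <- function(x, ...) {
  cat(sprintf("<window_plan> L = %d samples, step = %d, K = %d windows (fs = %g Hz)\n",
              x$L_samples, x$s_samples, x$K, x$fs))
  invisible(x)
}

# Extract window k (1-based) as a plain numeric vector.
.window_at <- function(samples, plan, k) {
  start <- (k - 1L) * plan$s_samples + 1L
  samples[start:(start + plan$L_samples - 1L)]
}

#' Z-score a window (population standard deviation)
#'
#' Centers and scales a window to mean 0 and population (1/N) standard
#' deviation 1. Near-constant windows, where the standard deviation falls
#' below a scale-aware guard `1e-12 * max(1, max(abs(window)))`, map to all
#' zeros instead of blowing up.
#'
#' @param w Numeric vector of length >= 2.
#' @return The normalized window.
#' @export
zscore_window <- function(w) {
  if (length(w) < 2L) stop("window must have length >= 2")
  m <- mean(w)
  sd_pop <- sqrt(mean((w - m)^2))
  eps <- 1e-12 * max(1, max(abs(w)))
  if (sd_pop < eps) return(rep(0, length(w)))
  (w - m) / sd_pop
}
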