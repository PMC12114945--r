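# Discrete analytic signal via the FFT half-spectrum method:
# zero the negative frequencies, double the positive ones.
.analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Phase unwrapping: remove 2*pi jumps from a wrapped phase sequence.
.unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(p[1L], p[1L] + cumsum(d))
}

#' Instantaneous amplitude and frequency of one IMF
#'
#' Builds the analytic signal `z = imf + i * H(imf)` by the FFT method and
#' derives the instantaneous amplitude `A = |z|` and instantaneous frequency
#' `f = (1/2pi) dphi/dt` from the unwrapped phase by central differences
#' (one-sided at the ends). A validity mask excludes the first and last
#' `edge_exclude` fraction of samples (Hilbert end effects) and any sample
#' whose frequency estimate is non-finite, non-positive, or at/above
#' Nyquist — such values are spline/Hilbert artifacts, not signal content.
#'
#' @param imf Numeric vector, length >= 8.
#' @param fs Sampling rate in Hz.
#' @param edge_exclude Fraction of samples masked out at each end
#'   (default 0.05).
#' @return An object of class `inst_attrs`: `amplitude`, `frequency` (Hz),
#'   `valid` (logical mask), `fs`.
#' @examples
#' t <- seq(0, 2, by = 1 / 1500)
#' a <- analytic_attrs(cos(2 * pi * 100 * t), fs = 1500)
#' range(a$frequency[a$valid])  # ~100 Hz
#' @export
analytic_attrs <- function(imf, fs, edge_exclude = 0.05) {
  n <- length(imf)
  if (n < 8L) stop("IMF too short for instantaneous attributes (need >= 8)")
  z <- .analytic_signal(imf)
  A <- Mod(z)
  phi <- .unwrap_phase(Arg(z))
  f <- numeric(n)
  f[2L:(n - 1L)] <- (phi[3L:n] - phi[1L:(n - 2L)]) * fs / (4 * pi)
  f[1L] <- (phi[2L] - phi[1L]) * fs / (2 * pi)
  f[n] <- (phi[n] - phi[n - 1L]) * fs / (2 * pi)
  edge <- floor(n * edge_exclude)
  valid <- is.finite(f) & f > 0 & f < fs / 2
  if (edge > 0L) {
    valid[seq_len(edge)] <- FALSE
    valid[seq.int(n - edge + 1L, n)] <- FALSE
  }
  structure(list(amplitude = A, frequency = f, valid = valid, fs = fs),
            class = "inst_attrs")
}

#' Hilbert marginal spectrum
#'
#' Accumulates, for every IMF and every valid sample, the instantaneous
#' amplitude times the sample period `1/fs` into the equal-width frequency
#' bin containing that sample's instantaneous frequency — a Riemann-sum
#' version of integrating the Hilbert spectrum along the time axis. Samples
#' at or above `f_max` fall into the last bin.
#'
#' @param attrs A single `inst_attrs` or a list of them (one per IMF).
#' @param fs Sampling rate in Hz.
#' @param n_bins Number of equal-width bins over `[0, f_max]` (default 45,
#'   i.e. 10 Hz resolution over the default pass band).
#' @param f_max Upper frequency edge in Hz (default 450; must not exceed
#'   Nyquist).
#' @param power If `TRUE`, accumulate squared amplitude (energy) instead of
#'   amplitude. Default `FALSE`: the marginal spectrum is a cumulative
#'   amplitude-per-frequency measure.
#' @return An object of class `marginal_spectrum`: `h` (length `n_bins`,
#'   units signal-units x seconds) and `bin_edges` (length `n_bins + 1`).
#' @export
marginal_spectrum <- function(attrs, fs, n_bins = 45L, f_max = 450, power = FALSE) {
  if (inherits(attrs, "inst_attrs")) attrs <- list(attrs)
  if (n_bins < 2L) stop("need at least 2 bins")
  if (!(f_max > 0 && f_max <= fs / 2)) stop("f_max must lie in (0, fs/2]")
  width <- f_max / n_bins
  h <- numeric(n_bins)
  used <- 0L
  dt <- 1 / fs
  for (a in attrs) {
    idx <- which(a$valid)
    if (length(idx) == 0L) next
    used <- used + length(idx)
    f <- a$frequency[idx]
    w <- a$amplitude[idx] * dt
    if (power) w <- a$amplitude[idx]^2 * dt
    bin <- pmin(floor(f / width) + 1L, n_bins)
    acc <- rowsum(w, bin)
    h[as.integer(rownames(acc))] <- h[as.integer(rownames(acc))] + acc[, 1L]
  }
  if (used == 0L) stop("empty spectrum: no usable samples in any IMF")
  structure(list(h = h, bin_edges = seq(0, f_max, length.out = n_bins + 1L)),
            class = "marginal_spectrum")
}

#' @export
print.marginal_spectrum <- function(x, ...) {
  peak <- which.max(x$h)
  cat(sprintf(
    "<marginal_spectrum> %d bins over [%g, %g] Hz; peak bin center %.1f Hz\n",
    length(x$h), x$bin_edges[1L], x$bin_edges[length(x$bin_edges)],
    (x$bin_edges[peak] + x$bin_edges[peak + 1L]) / 2
  ))
  invisible(x)
}

# Full per-window pipeline: EMD -> instantaneous attributes -> marginal
# spectrum. Returns NULL when the window yields no usable spectrum (e.g. a
# constant window with no IMFs); callers decide how to fill the gap.
.window_spectrum <- function(w, fs, params) {
  d <- emd(w, max_imfs = params$emd$max_imfs, sd_tol = params$emd$sd_tol,
           max_iters = params$emd$max_sift_iters)
  if (length(d$imfs) == 0L) return(NULL)
  attrs <- lapply(d$imfs, analytic_attrs, fs = fs,
                  edge_exclude = params$hht$edge_exclude)
  tryCatch(
    marginal_spectrum(attrs, fs = fs, n_bins = params$hht$n_bins,
                      f_max = params$hht$f_max_hz,
                      power = params$hht$power_spectrum),
    error = function(e) NULL
  )
}
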