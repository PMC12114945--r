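#' Locate local extrema of a sampled signal
#'
#' Strict sign changes of the first difference define extrema; a flat run
#' (plateau) bounded by opposite slopes counts as a single extremum at the
#' plateau midpoint. Endpoints are never extrema.
#'
#' @param x Numeric vector.
#' @return List with integer vectors `maxima` and `minima` (1-based indices).
#' @export
find_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) return(list(maxima = integer(0), minima = integer(0)))
  d <- sign(diff(x))
  nz <- which(d != 0)
  if (length(nz) < 2L) return(list(maxima = integer(0), minima = integer(0)))
  maxima <- integer(0); minima <- integer(0)
  for (j in seq_len(length(nz) - 1L)) {
    i1 <- nz[j]; i2 <- nz[j + 1L]
    if (d[i1] == d[i2]) next
    # extremum lies on the (possibly flat) stretch between slopes i1 and i2
    idx <- as.integer((i1 + 1L + i2) %/% 2L)
    if (d[i1] > 0) maxima <- c(maxima, idx) else minima <- c(minima, idx)
  }
  list(maxima = maxima, minima = minima)
}

# Count sign changes, ignoring exact zeros.
.zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(diff(s) != 0L)
}

#' Check the intrinsic-mode-function criterion
#'
#' An IMF's numbers of extrema and zero-crossings differ by at most one.
#'
#' @param x Numeric vector.
#' @return Logical scalar.
#' @export
is_imf <- function(x) {
  ex <- find_extrema(x)
  n_ex <- length(ex$maxima) + length(ex$minima)
  abs(n_ex - .zero_crossings(x)) <= 1L
}

# Interpolate an envelope through extrema with mirrored boundary knots.
# Natural cubic spline with >= 4 knots, linear interpolation otherwise.
.envelope <- function(idx, x) {
  n <- length(x)
  k <- length(idx)
  # mirror the two nearest extrema about each end to tame end swings
  first2 <- idx[seq_len(min(2L, k))]           # increasing
  last2 <- idx[seq.int(k, by = -1L, length.out = min(2L, k))]  # decreasing
  xi <- c(2L - rev(first2), idx, 2L * n - last2)
  yi <- c(x[rev(first2)], x[idx], x[last2])
  ord <- order(xi)
  xi <- xi[ord]; yi <- yi[ord]
  keep <- !duplicated(xi)
  xi <- xi[keep]; yi <- yi[keep]
  if (length(xi) >= 4L) {
    stats::spline(xi, yi, xout = seq_len(n), method = "natural")$y
  } else {
    stats::approx(xi, yi, xout = seq_len(n), rule = 2)$y
  }
}

#' Local mean from upper and lower spline envelopes
#'
#' Computes `m(t) = (u(t) + l(t)) / 2` where `u` and `l` are cubic-spline
#' envelopes through the local maxima and minima, with the two extrema
#' nearest each end mirrored outside the signal before fitting.
#'
#' @param x Numeric vector.
#' @return The local-mean vector, or `NULL` when `x` has fewer than 2
#'   interior maxima or fewer than 2 interior minima (a monotonic or trend
#'   component; the caller stops decomposing).
#' @export
envelope_mean <- function(x) {
  ex <- find_extrema(x)
  if (length(ex$maxima) < 2L || length(ex$minima) < 2L) return(NULL)
  u <- .envelope(ex$maxima, x)
  l <- .envelope(ex$minima, x)
  (u + l) / 2
}

#' Sift one intrinsic mode function
#'
#' Iterates `h <- h - m(h)` from `h = x` until the Cauchy criterion
#' `sum((h_prev - h_new)^2) / sum(h_prev^2) < sd_tol` is met *and* the
#' candidate passes both parts of the IMF definition — the
#' extrema/zero-crossing count check and a near-zero residual local mean
#' (interior mean `|m|` at most 10% of the candidate's interior RMS) — or
#' `max_iters` is reached (flagged via `converged`/`is_imf` in the
#' result). An all-zero (or envelope-exhausted) candidate returns
#' immediately.
#'
#' @param x Numeric vector.
#' @param sd_tol Cauchy stopping tolerance (classical choice 0.2-0.3).
#' @param max_iters Iteration cap per IMF.
#' @return List with `imf`, `iters`, `converged` (Cauchy criterion met) and
#'   `is_imf` (extrema/zero-crossing check on the result).
#' @export
sift_imf <- function(x, sd_tol = 0.2, max_iters = 100L) {
  h <- x
  iters <- 0L
  converged <- FALSE
  m <- envelope_mean(h)
  repeat {
    denom <- sum(h^2)
    if (denom == 0) { converged <- TRUE; break }
    if (is.null(m)) break
    h_new <- h - m
    iters <- iters + 1L
    cauchy <- sum((h - h_new)^2) / denom < sd_tol
    h <- h_new
    m <- envelope_mean(h)
    if (cauchy && is_imf(h) && .local_mean_ok(h, m)) { converged <- TRUE; break }
    if (iters >= max_iters) break
  }
  list(imf = h, iters = iters, converged = converged, is_imf = is_imf(h))
}

# Second half of the IMF definition: the residual local mean must be small
# relative to the component (checked on interior samples; envelope end
# effects are excluded).
.local_mean_ok <- function(h, m, frac = 0.1) {
  if (is.null(m)) return(TRUE)
  n <- length(h)
  e <- max(1L, floor(n * 0.1))
  i <- (e + 1L):(n - e)
  rms <- sqrt(mean(h[i]^2))
  rms == 0 || mean(abs(m[i])) <= frac * rms
}

#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions by recursive sifting:
#' `c_i` is sifted from the running residual and subtracted, until the
#' residual is monotonic (fewer than 2 interior maxima or minima) or
#' `max_imfs` components have been extracted. The residual is defined as the
#' remainder, so the decomposition reconstructs the input exactly:
#' `sum(imfs) + residual == x`.
#'
#' @param x An `emg_signal` or numeric vector of length >= 16.
#' @param max_imfs Maximum number of IMFs (default 6).
#' @param sd_tol,max_iters Passed to [sift_imf()].
#' @return An object of class `imf_set`: `imfs` (list of numeric vectors,
#'   possibly empty), `residual`, `n_sift_iters`, `converged`, `imf_ok`.
#' @examples
#' t <- seq(0, 2, by = 1 / 1500)
#' d <- emd(sin(2 * pi * 50 * t) + sin(2 * pi * 5 * t))
#' length(d$imfs)
#' @export
emd <- function(x, max_imfs = 6L, sd_tol = 0.2, max_iters = 100L) {
  samples <- if (inherits(x, "emg_signal")) x$samples else as.numeric(x)
  if (length(samples) < 16L) stop("signal too short for EMD (need >= 16 samples)")
  imfs <- list()
  iters <- integer(0); conv <- logical(0); ok <- logical(0)
  r <- samples
  while (length(imfs) < max_imfs) {
    if (is.null(envelope_mean(r))) break  # monotonic / trend residual
    s <- sift_imf(r, sd_tol = sd_tol, max_iters = max_iters)
    imfs[[length(imfs) + 1L]] <- s$imf
    iters <- c(iters, s$iters); conv <- c(conv, s$converged)
    ok <- c(ok, s$is_imf)
    r <- r - s$imf
  }
  structure(list(imfs = imfs, residual = r, n_sift_iters = iters,
                 converged = conv, imf_ok = ok),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMFs + residual (%d samples); sift iters: %s\n",
              length(x$imfs), length(x$residual),
              paste(x$n_sift_iters, collapse = ", ")))
  invisible(x)
}
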