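#' Normalized Shannon entropy of a marginal spectrum
#'
#' Normalizes the binned marginal spectrum to a probability vector
#' `p_i = h_i / sum(h)`, computes the Shannon entropy
#' `raw = -sum(p_i * log(p_i))` in nats (with the `0 * log 0 = 0` limit
#' convention for empty bins), and scales by the maximum attainable value
#' `log(n)`, where `n` is the total bin count. The result lies in `[0, 1]`:
#' 0 when all mass sits in one bin (spectrally regular), 1 when mass is
#' spread uniformly (maximally complex). The value is invariant to
#' amplitude scaling and to bin permutation, which is what makes the
#' downstream detector threshold-free.
#'
#' @param spectrum A `marginal_spectrum` or a non-negative numeric vector of
#'   bin masses with at least 2 bins and positive total mass.
#' @return An object of class `mse_value`: `value` (normalized, unitless),
#'   `raw` (nats), `n_bins_used` (bins with positive mass).
#' @examples
#' compute_mse(c(1, 1, 1, 1))$value  # 1
#' compute_mse(c(0, 0, 5, 0))$value  # 0
#' compute_mse(c(3, 1))$value        # 0.811278
#' @export
compute_mse <- function(spectrum) {
  h <- if (inherits(spectrum, "marginal_spectrum")) spectrum$h else as.numeric(spectrum)
  n <- length(h)
  if (n < 2L) stop("need at least 2 bins")
  if (any(h < 0)) stop("bin masses must be non-negative")
  total <- sum(h)
  if (total <= 0) stop("undefined entropy: all-zero spectrum")
  p <- h / total
  pos <- p > 0
  if (all(pos) && all(h == h[1L])) {
    # uniform mass: the maximum is attained exactly, bypass roundoff
    return(structure(list(value = 1, raw = log(n), n_bins_used = n),
                     class = "mse_value"))
  }
  raw <- -sum(p[pos] * log(p[pos]))
  value <- raw / log(n)
  # clamp the roundoff at the uniform end so the [0, 1] contract is exact
  value <- min(max(value, 0), 1)
  structure(list(value = value, raw = raw, n_bins_used = sum(pos)),
            class = "mse_value")
}

#' @export
print.mse_value <- function(x, ...) {
  cat(sprintf("<mse_value> %.6f (raw %.6f nats, %d bins used)\n",
              x$value, x$raw, x$n_bins_used))
  invisible(x)
}
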