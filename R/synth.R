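#' Specification of a surrogate slow-activation sEMG recording
#'
#' Describes one synthetic recording: a quiescent stochastic baseline
#' followed by a gradually rising activation component with known onset
#' time. The activation component is spectrally shaped like surface EMG
#' (a band-limited stochastic process whose power spectrum peaks around
#' 60-120 Hz, the classical two-pole sEMG spectrum model), while the
#' baseline is spectrally flat within the analysis band — emulating the
#' transition from instrumentation noise to muscle activity that gives
#' real slow activations their gradual spectral redistribution.
#'
#' @param fs Sampling rate in Hz (default 1500).
#' @param duration Total duration in seconds (default 6).
#' @param t_on True activation onset (start of the envelope ramp), s.
#' @param rise Envelope rise duration in seconds.
#' @param snr_db Activation-to-baseline amplitude ratio,
#'   `20 * log10(sigma_a / sigma_b)` with `sigma_b = 1`; `-Inf` yields a
#'   pure-baseline (no-activation) recording.
#' @param band Band limits `(low, high)` in Hz applied to both components.
#' @param seed Integer RNG seed; generation is bitwise reproducible.
#' @param shape `"emg"` (default) shapes the activation component with the
#'   two-pole sEMG spectrum; `"flat"` leaves it spectrally flat in `band`
#'   (then the activation differs from baseline only in scale, which no
#'   scale-free detector can see — useful for null checks).
#' @param shape_freqs Low/high characteristic frequencies of the sEMG
#'   spectrum model in Hz (default `c(60, 120)`).
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(fs = 1500, duration = 6, t_on = 2, rise = 1,
                       snr_db = 10, band = c(20, 450), seed = 1L,
                       shape = c("emg", "flat"), shape_freqs = c(60, 120)) {
  shape <- match.arg(shape)
  stopifnot(fs > 0, duration > 0, is.finite(snr_db) || snr_db == -Inf,
            band[1] > 0, band[2] > band[1], band[2] < fs / 2)
  if (!(t_on > 0 && t_on + rise < duration))
    stop("need 0 < t_on < t_on + rise < duration")
  structure(list(fs = fs, duration = duration, t_on = t_on, rise = rise,
                 snr_db = snr_db, band = band, seed = as.integer(seed),
                 shape = shape, shape_freqs = shape_freqs),
            class = "synth_spec")
}

# Run a generator expression under a local RNG state.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

# Amplitude response of the two-pole sEMG power-spectrum model
# PSD(f) ~ fh^4 f^2 / ((f^2 + fl^2) (f^2 + fh^2)^2).
.emg_shape_gain <- function(f, fl, fh) {
  fh^2 * abs(f) / (sqrt(f^2 + fl^2) * (f^2 + fh^2))
}

# Spectrally shape white noise by a real frequency-domain gain |H(f)|.
.shape_noise <- function(x, fs, gain_fun) {
  n <- length(x)
  f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
  H <- gain_fun(f)
  Re(stats::fft(stats::fft(x) * H, inverse = TRUE) / n)
}

# Smoothstep envelope: 0 before t_on, 3u^2 - 2u^3 on the ramp, 1 after.
.smoothstep_envelope <- function(t, t_on, rise) {
  u <- (t - t_on) / rise
  u <- pmin(pmax(u, 0), 1)
  3 * u^2 - 2 * u^3
}

#' Generate a surrogate slow-activation sEMG signal
#'
#' Produces `x(t) = b(t) + e(t) * a(t)`: `b` is seeded Gaussian noise
#' band-passed to `spec$band` and scaled to unit standard deviation
#' (`sigma_b = 1`); `a` is independent seeded Gaussian noise, spectrally
#' shaped per `spec$shape`, band-passed, and scaled to
#' `sigma_a = 10^(snr_db / 20)`; and the envelope `e` is 0 before `t_on`,
#' the smoothstep `3u^2 - 2u^3` over the ramp, and 1 afterwards. The
#' baseline persists during activation, as in real recordings. Generation
#' is bitwise reproducible from `spec$seed` and leaves the caller's RNG
#' state untouched.
#'
#' @param spec A [synth_spec()].
#' @return A list with `signal` (`emg_signal`), `t_on` (ramp start, s),
#'   `t_mid` (ramp midpoint, s), and `spec`.
#' @export
generate_emg <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- as.integer(round(spec$duration * spec$fs)) + 1L
  t <- (seq_len(n) - 1L) / spec$fs
  sigma_a <- if (spec$snr_db == -Inf) 0 else 10^(spec$snr_db / 20)
  samples <- .with_seed(spec$seed, {
    bf <- signal::butter(4L, spec$band / (spec$fs / 2), type = "pass")
    b <- .filtfilt_refl(bf$b, bf$a, stats::rnorm(n))
    b <- b / stats::sd(b)
    a <- stats::rnorm(n)
    if (spec$shape == "emg") {
      fl <- spec$shape_freqs[1]; fh <- spec$shape_freqs[2]
      a <- .shape_noise(a, spec$fs, function(f) .emg_shape_gain(f, fl, fh))
    }
    a <- .filtfilt_refl(bf$b, bf$a, a)
    a <- a / stats::sd(a)
    e <- .smoothstep_envelope(t, spec$t_on, spec$rise)
    b + e * (sigma_a * a)
  })
  list(signal = emg_signal(samples, fs = spec$fs, t0 = 0),
       t_on = spec$t_on, t_mid = spec$t_on + spec$rise / 2, spec = spec)
}

#' Build a labelled benchmark set of synthetic recordings
#'
#' Generates `n` recordings: the first half are activation cases with rise
#' duration drawn uniformly from `rise_range` and onset drawn uniformly
#' from `[1, duration - rise - 1]` seconds; the second half are
#' no-activation cases (pure baseline). Signal `i` uses seed
#' `seed0 + i - 1`, so the whole set is deterministic.
#'
#' @param n Number of recordings (>= 1).
#' @param rise_range Two-element range of rise durations, s.
#' @param snr_db SNR of the activation cases, dB.
#' @param seed0 Base seed.
#' @param duration,fs Recording duration (s) and sampling rate (Hz).
#' @return A list of entries, each with `id`, `signal`, `t_on` (`NA` for
#'   negatives), `t_mid`, `rise`, `snr_db`, `seed`.
#' @export
make_benchmark_set <- function(n, rise_range = c(0.5, 2.0), snr_db = 10,
                               seed0 = 1000L, duration = 6, fs = 1500) {
  stopifnot(n >= 1L)
  n_pos <- ceiling(n / 2)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    seed <- as.integer(seed0 + i - 1L)
    if (i <= n_pos) {
      draws <- .with_seed(seed, {
        rise <- stats::runif(1, rise_range[1], rise_range[2])
        t_on <- stats::runif(1, 1, duration - rise - 1)
        c(rise, t_on)
      })
      sp <- synth_spec(fs = fs, duration = duration, t_on = draws[2],
                       rise = draws[1], snr_db = snr_db, seed = seed)
      gen <- generate_emg(sp)
      out[[i]] <- list(id = i, signal = gen$signal, t_on = gen$t_on,
                       t_mid = gen$t_mid, rise = draws[1], snr_db = snr_db,
                       seed = seed)
    } else {
      sp <- synth_spec(fs = fs, duration = duration, t_on = duration / 3,
                       rise = 0.5, snr_db = -Inf, seed = seed)
      gen <- generate_emg(sp)
      out[[i]] <- list(id = i, signal = gen$signal, t_on = NA_real_,
                       t_mid = NA_real_, rise = NA_real_, snr_db = -Inf,
                       seed = seed)
    }
  }
  out
}

#' Write a benchmark set's ground truth as a sidecar table
#'
#' @param dataset Output of [make_benchmark_set()].
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_benchmark_truth <- function(dataset, path) {
  df <- data.frame(
    id = vapply(dataset, `[[`, numeric(1), "id"),
    t_on = vapply(dataset, `[[`, numeric(1), "t_on"),
    rise = vapply(dataset, `[[`, numeric(1), "rise"),
    snr_db = vapply(dataset, `[[`, numeric(1), "snr_db"),
    seed = vapply(dataset, function(d) as.numeric(d$seed), numeric(1))
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
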