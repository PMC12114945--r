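test_that("generation is bitwise reproducible and leaves the RNG alone", {
  sp <- synth_spec(duration = 3, t_on = 1, rise = 0.5, seed = 11)
  set.seed(999)
  before <- .Random.seed
  g1 <- generate_emg(sp)
  expect_identical(.Random.seed, before)
  g2 <- generate_emg(sp)
  expect_identical(g1$signal$samples, g2$signal$samples)
  g3 <- generate_emg(synth_spec(duration = 3, t_on = 1, rise = 0.5, seed = 12))
  expect_false(identical(g1$signal$samples, g3$signal$samples))
})

test_that("the no-activation sentinel yields pure baseline", {
  neg <- generate_emg(synth_spec(duration = 3, t_on = 1, rise = 0.5,
                                 snr_db = -Inf, seed = 4))
  pos <- generate_emg(synth_spec(duration = 3, t_on = 1, rise = 0.5,
                                 snr_db = 10, seed = 4))
  n <- length(neg$signal$samples)
  third <- floor(n / 3)
  # identical seed: the baseline component is shared, activation absent
  expect_identical(neg$signal$samples[1:third], pos$signal$samples[1:third])
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(abs(rms(neg$signal$samples) - 1), 0.1)
})

test_that("a high-SNR ramp leaves the pre-onset region quiet", {
  gen <- generate_emg(synth_spec(duration = 5, t_on = 2, rise = 1,
                                 snr_db = 80, seed = 2))
  s <- gen$signal$samples
  fs <- gen$signal$fs
  rms <- function(v) sqrt(mean(v^2))
  pre <- rms(s[1:floor(1.9 * fs)])
  post <- rms(s[ceiling(3.1 * fs):length(s)])
  expect_lte(pre / post, 0.01)
})

test_that("generated power stays inside the shaping band", {
  gen <- generate_emg(synth_spec(duration = 4, t_on = 1, rise = 1,
                                 snr_db = 10, seed = 31))
  s <- gen$signal$samples
  n <- length(s)
  P <- Mod(fft(s))[2:floor(n / 2)]^2
  f <- (1:(floor(n / 2) - 1)) * 1500 / n
  in_band <- f >= 20 & f <= 450
  expect_gte(sum(P[in_band]) / sum(P), 0.90)
})

test_that("the smoothstep envelope is monotone over the ramp", {
  t <- seq(0, 5, by = 1e-3)
  e <- emgonset:::.smoothstep_envelope(t, 2, 1.5)
  expect_true(all(diff(e) >= 0))
  expect_identical(e[t < 2], rep(0, sum(t < 2)))
  expect_identical(e[t > 3.5], rep(1, sum(t > 3.5)))
})

test_that("empirical SNR matches the asymptotic value implied by snr_db", {
  for (snr in c(6, 10, 16)) {
    gen <- generate_emg(synth_spec(duration = 6, t_on = 1.5, rise = 0.5,
                                   snr_db = snr, seed = 50 + snr))
    s <- gen$signal$samples
    fs <- gen$signal$fs
    rms <- function(v) sqrt(mean(v^2))
    base <- rms(s[1:floor(1.4 * fs)])
    tail_ <- rms(s[ceiling(2.5 * fs):length(s)])
    sigma_a <- 10^(snr / 20)
    asymptotic <- 20 * log10(sqrt(1 + sigma_a^2))  # active tail carries both
    expect_lte(abs(20 * log10(tail_ / base) - asymptotic), 1.5)
  }
})

test_that("benchmark sets are balanced, bounded and deterministic", {
  ds <- make_benchmark_set(4, rise_range = c(0.5, 2.0), seed0 = 100)
  expect_length(ds, 4)
  truths <- vapply(ds, `[[`, numeric(1), "t_on")
  expect_identical(sum(!is.na(truths)), 2L)
  expect_identical(sum(is.na(truths)), 2L)
  seeds <- vapply(ds, `[[`, integer(1), "seed")
  expect_identical(seeds, 100:103)
  rises <- vapply(ds, `[[`, numeric(1), "rise")
  expect_true(all(rises[!is.na(rises)] >= 0.5 & rises[!is.na(rises)] <= 2.0))

  ds2 <- make_benchmark_set(4, rise_range = c(0.5, 2.0), seed0 = 100)
  for (i in 1:4)
    expect_identical(ds[[i]]$signal$samples, ds2[[i]]$signal$samples)
})

test_that("spec invariants are enforced at construction", {
  expect_error(synth_spec(t_on = 5, rise = 2, duration = 6), "t_on")
  expect_error(synth_spec(band = c(100, 800), fs = 1500), "band")
})
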