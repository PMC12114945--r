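plan_of <- function(K, s_samples = 96L, fs = 1500, t0 = 0, L = 192L) {
  structure(list(L_samples = L, s_samples = s_samples, K = as.integer(K),
                 t0 = t0, fs = fs), class = "window_plan")
}

test_that("trend smoothing averages with edge truncation", {
  expect_equal(smooth_trend(c(0, 0, 1, 0, 0), 3), c(0, 1/3, 1/3, 1/3, 0))
  M <- runif(11)
  expect_identical(smooth_trend(M, 1), M)
  expect_equal(smooth_trend(rep(0.4, 9), 5), rep(0.4, 9))
  expect_error(smooth_trend(M, 4), "odd")
  expect_error(smooth_trend(M, 13), "between 1 and")
})

test_that("the steepest-drop rule reproduces the worked micro-example", {
  T <- c(0.90, 0.88, 0.85, 0.60, 0.55)
  r <- detect_onset(T, plan_of(5, s_samples = 96L, fs = 1500))
  expect_identical(r$k_star, 3L)
  expect_identical(r$t_star, 0.128)
  expect_equal(r$diagnostics$delta, c(-0.02, -0.03, -0.25, -0.05))
})

test_that("ties break to the earliest window and t0 carries through", {
  r <- detect_onset(c(1.0, 0.5, 0.0, -0.5), plan_of(4, t0 = 2.5))
  expect_identical(r$k_star, 1L)
  expect_identical(r$t_star, 2.5)
  expect_error(detect_onset(0.5, plan_of(1)), "at least 2")
})

test_that("the steepest-drop index matches an exhaustive scan", {
  set.seed(55)
  for (i in 1:300) {
    K <- sample(2:50, 1)
    T <- round(runif(K), sample(1:3, 1))  # rounding forces frequent ties
    r <- detect_onset(T, plan_of(K))
    d <- vapply(1:(K - 1), function(k) T[k + 1] - T[k], numeric(1))
    best <- which(d == min(d))[1]
    expect_identical(r$k_star, as.integer(best))
  }
})

test_that("rejection fires only on shallow trends", {
  flat <- c(0.90, 0.895, 0.90, 0.905, 0.90)
  expect_true(is.na(detect_onset(flat, plan_of(5), reject_delta = 0.02)$t_star))
  steep <- c(0.9, 0.9, 0.8, 0.8)
  expect_false(is.na(detect_onset(steep, plan_of(4), reject_delta = 0.02)$t_star))
  # delta = 0 always detects
  expect_false(is.na(detect_onset(flat, plan_of(5))$t_star))
})

test_that("entropy sequences are stable on stationary inputs", {
  gen <- generate_emg(synth_spec(duration = 3, t_on = 1, rise = 0.5,
                                 snr_db = -Inf, seed = 3))
  M <- entropy_sequence(gen$signal)$M
  expect_length(M, plan_windows(gen$signal)$K)
  expect_lte(sd(M), 0.1)

  x <- emg_signal(tone(100, dur = 3), fs = 1500)
  Mt <- entropy_sequence(x)$M
  expect_lte(max(Mt) - min(Mt), 0.15)

  one <- emg_signal(tone(100, dur = 1)[1:192], fs = 1500)
  expect_length(entropy_sequence(one)$M, 1)
})

test_that("windows without a usable spectrum inherit the previous value", {
  gen <- generate_emg(synth_spec(duration = 2, t_on = 1, rise = 0.5,
                                 snr_db = -Inf, seed = 9))
  s <- gen$signal$samples
  s[193:480] <- 0  # windows 3 and 4 become exactly constant
  x <- emg_signal(s, fs = 1500)
  M <- entropy_sequence(x)$M
  expect_identical(M[3], M[2])
  expect_true(all(is.finite(M)))
  expect_error(entropy_sequence(emg_signal(rep(0, 1000), fs = 1500)),
               "unusable")
})

test_that("the full detector recovers a strong activation and is deterministic", {
  gen <- strong_activation(seed = 7)
  r1 <- detect(gen$signal, mode = "mse")
  r2 <- detect(gen$signal, mode = "mse")
  expect_identical(r1$t_star, r2$t_star)
  expect_lt(abs(r1$t_star - gen$t_on), 0.35)
  expect_identical(r1$method, "mse")
  # onset lies inside the recording
  expect_gte(r1$t_star, gen$signal$t0)
  expect_lte(r1$t_star, gen$signal$t0 + emg_duration(gen$signal))
})

test_that("ablation modes run and differ from the full detector as defined", {
  gen <- strong_activation(seed = 12)
  full <- detect(gen$signal, mode = "mse")
  only <- detect(gen$signal, mode = "mse-only")
  en <- detect(gen$signal, mode = "energy-slope")
  nw <- detect(gen$signal, mode = "mse-nowindow")
  expect_identical(only$method, "mse-only")
  # mse-only is the global minimum of the same smoothed trend
  Tr <- only$diagnostics$trend
  plan <- plan_windows(bandpass(gen$signal))
  s_sec <- plan$s_samples / plan$fs
  expect_equal(only$t_star, (which.min(Tr) - 1) * s_sec)
  # energy-slope picks the steepest rise of the normalized energy trend
  dE <- diff(en$diagnostics$trend)
  expect_equal(en$t_star, (which.max(dE) - 1) * s_sec)
  expect_length(nw$diagnostics$M, plan$K)
  for (r in list(full, only, en, nw)) {
    expect_s3_class(r, "onset_result")
    expect_false(is.na(r$t_star))
  }
})

test_that("slope and minimum detectors diverge on a rebounding trend", {
  T <- c(0.9, 0.8, 0.3, 0.4)
  slope_k <- detect_onset(T, plan_of(4))$k_star
  min_k <- which.min(T)
  expect_identical(slope_k, 2L)
  expect_identical(min_k, 3L)
})

test_that("prepending baseline shifts the detected onset by the same amount", {
  gen <- strong_activation(seed = 21)
  filtered <- bandpass(gen$signal)
  pad_gen <- generate_emg(synth_spec(duration = 3, t_on = 1, rise = 0.5,
                                     snr_db = -Inf, seed = 77))
  q <- 5L
  pad <- bandpass(pad_gen$signal)$samples[seq_len(q * 96L)]
  shifted <- emg_signal(c(pad, filtered$samples), fs = 1500)
  p <- emg_params(filter.enabled = FALSE)
  r0 <- detect(filtered, mode = "mse", params = p)
  r1 <- detect(shifted, mode = "mse", params = p)
  s_sec <- 96 / 1500
  expect_lte(abs(r1$t_star - (r0$t_star + q * s_sec)), s_sec)
})
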