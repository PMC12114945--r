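test_that("the TKE operator matches its closed form on tones", {
  expect_equal(tke_operator(c(0, 1, 0, -1, 0))[2:4], rep(1, 3),
               tolerance = 1e-12)
  expect_equal(tke_operator(rep(3, 10))[2:9], rep(0, 8))
  n <- 0:199
  for (A in c(1, 2)) for (Om in c(pi / 4, pi / 2)) {
    psi <- tke_operator(A * cos(Om * n))
    expect_lt(max(abs(psi[2:199] - A^2 * sin(Om)^2)), 1e-9)
  }
  expect_error(tke_operator(c(1, 2)), "at least 3")
})

test_that("the relative threshold detector crosses a linear ramp at 30%", {
  fs <- 1500
  t <- seq(0, 2, by = 1 / fs)
  ramp <- pmin(t, 1)  # envelope rises 0 -> 1 over [0, 1] s then holds
  x <- emg_signal(ramp * cos(2 * pi * 100 * t), fs = fs)
  r <- detect_threshold(x)
  expect_lt(abs(r$t_star - 0.3), 0.03)
  r10 <- detect_threshold(emg_signal(10 * x$samples, fs = fs))
  expect_identical(r10$t_star, r$t_star)  # scale-free
  expect_error(detect_threshold(emg_signal(rep(2, 100), fs = fs)), "constant")
})

test_that("the threshold detector tracks a step within the envelope lag", {
  fs <- 1500
  t <- seq(0, 2, by = 1 / fs)
  x <- emg_signal(ifelse(t >= 0.5, 1, 0) * cos(2 * pi * 100 * t), fs = fs)
  r <- detect_threshold(x)
  expect_lt(abs(r$t_star - 0.5), 0.05)
})

test_that("the TKE detector localizes an abrupt amplitude step", {
  gen <- generate_emg(synth_spec(duration = 3, t_on = 1, rise = 0.02,
                                 snr_db = 14, seed = 41, shape = "flat"))
  r <- detect_tke(gen$signal)
  expect_false(is.na(r$t_star))
  expect_lt(abs(r$t_star - 1.0), 0.1)
  r10 <- detect_tke(emg_signal(10 * gen$signal$samples, fs = 1500))
  expect_equal(r10$t_star, r$t_star)
})

test_that("the TKE detector stays silent on pure baseline noise", {
  for (s in 1:20) {
    gen <- generate_emg(synth_spec(duration = 3, t_on = 1, rise = 0.5,
                                   snr_db = -Inf, seed = 1000 + s))
    expect_true(is.na(detect_tke(gen$signal)$t_star),
                label = paste("seed", 1000 + s))
  }
})

test_that("RMS windowing flags the first supra-threshold run", {
  fs <- 1500
  n <- 19 * 96 + 192
  amp <- rep(1, n)
  step_at <- 9 * 96 + 1  # left edge of window 10
  amp[step_at:n] <- 4
  x <- emg_signal(amp * cos(2 * pi * 100 * (0:(n - 1)) / fs), fs = fs)
  plan <- plan_windows(x)
  r <- detect_rms(x, plan = plan)
  # oracle: first window whose RMS exceeds the baseline threshold
  rms <- vapply(1:plan$K, function(k) {
    i <- (k - 1) * 96 + 1
    sqrt(mean(x$samples[i:(i + 191)]^2))
  }, numeric(1))
  B <- floor(0.3 / (96 / fs))
  thr <- mean(rms[1:B]) + 3 * sd(rms[1:B])
  expect_identical(r$k_star, as.integer(which(rms > thr)[1]))
  # detected onset within one window of the true step
  t_step <- (step_at - 1) / fs
  expect_lte(abs(r$t_star - t_step), 192 / fs)
})

test_that("the persistence rule suppresses single-window spikes", {
  fs <- 1500
  gen <- generate_emg(synth_spec(duration = 3, t_on = 1, rise = 0.5,
                                 snr_db = -Inf, seed = 5))
  s <- gen$signal$samples
  spike_win <- (12 * 192 + 1):(13 * 192)  # disjoint window 13 only
  s[spike_win] <- s[spike_win] * 6
  x <- emg_signal(s, fs = fs)
  plan <- plan_windows(x, overlap = 0)  # disjoint windows
  # a long quiescent reference keeps the threshold stable
  p1 <- baseline_params(consec = 1, baseline_ms = 1280)
  p2 <- baseline_params(consec = 2, baseline_ms = 1280)
  expect_false(is.na(detect_rms(x, p1, plan)$t_star))
  expect_true(is.na(detect_rms(x, p2, plan)$t_star))
})

test_that("wavelet detail energy tracks the same step as RMS windowing", {
  fs <- 1500
  n <- 19 * 96 + 192
  amp <- rep(1, n); amp[(9 * 96 + 1):n] <- 4
  x <- emg_signal(amp * cos(2 * pi * 100 * (0:(n - 1)) / fs), fs = fs)
  plan <- plan_windows(x)
  rw <- detect_wavelet(x, plan = plan)
  rr <- detect_rms(x, plan = plan)
  expect_false(is.na(rw$t_star))
  expect_lte(abs(rw$t_star - rr$t_star), 96 / fs)
  r10 <- detect_wavelet(emg_signal(10 * x$samples, fs = fs), plan = plan)
  expect_equal(r10$t_star, rw$t_star)
})

test_that("wavelet detection ignores sub-band drift and flat energy", {
  fs <- 1500
  t <- seq(0, 3, by = 1 / fs)
  drift <- emg_signal(sin(2 * pi * 1 * t), fs = fs)  # below all detail bands
  expect_true(is.na(detect_wavelet(drift)$t_star))
  expect_error(dwt_details(rnorm(8), levels = 4), "too short")
  expect_error(dwt_details(rnorm(64), wavelet = "haar"), "db4")
})

test_that("db4 detail filters annihilate constants", {
  d <- dwt_details(rep(1, 256), levels = 4)
  for (lev in d) expect_lt(max(abs(lev$coef)), 1e-12)
})
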