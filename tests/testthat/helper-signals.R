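# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

tone <- function(freq, fs = 1500, dur = 2, amp = 1, phase = 0) {
  t <- seq(0, dur, by = 1 / fs)
  amp * cos(2 * pi * freq * t + phase)
}

# Linear chirp sweeping f0 -> f1 over dur seconds.
chirp <- function(f0, f1, fs = 1500, dur = 2) {
  t <- seq(0, dur, by = 1 / fs)
  cos(2 * pi * (f0 * t + (f1 - f0) / (2 * dur) * t^2))
}

# Interior index range excluding a fraction at each edge.
interior <- function(n, frac = 0.1) {
  e <- max(1L, floor(n * frac))
  (e + 1L):(n - e)
}

# A well-behaved high-contrast activation fixture: robust entropy drop,
# used by unit tests that need reliable detection (the spec-condition
# benchmark lives in the acceptance tests).
strong_activation <- function(seed = 7, t_on = 2, rise = 0.4, snr_db = 20,
                              duration = 5) {
  generate_emg(synth_spec(duration = duration, t_on = t_on, rise = rise,
                          snr_db = snr_db, seed = seed))
}

write_tmp <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
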