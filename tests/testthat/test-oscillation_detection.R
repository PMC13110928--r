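fs <- 500
theta <- default_bands()$theta

test_that("FIR bandpass passes in-band tones and rejects out-of-band energy", {
  t <- seq(0, 20, by = 1 / fs)
  mid <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
  in_band <- bandpass(sin(2 * pi * 6 * t), theta, fs)
  expect_lt(abs(max(abs(in_band[mid])) - 1), 0.05)
  out_band <- bandpass(sin(2 * pi * 20 * t), theta, fs)
  expect_lt(max(abs(out_band[mid])), 0.1)
  dc <- bandpass(rep(1, length(t)), theta, fs)
  expect_lt(max(abs(dc[mid])), 0.01)
  expect_error(bandpass(sin(t), frequency_band("x", 200, 260, 1, 1), fs),
               "Nyquist")
})

test_that("zero-phase filtering preserves event timing", {
  t <- seq(0, 20, by = 1 / fs)
  x <- exp(-(t - 10)^2 / 0.5) * sin(2 * pi * 6 * t)
  y <- bandpass(x, theta, fs)
  # the filtered envelope must still peak at the input's 10 s centre
  expect_lt(abs(which.max(amplitude_envelope(y)) / fs - 10), 0.05)
})

test_that("analytic-signal envelope recovers amplitudes and modulators", {
  t <- seq(0, 10, by = 1 / fs)
  env <- amplitude_envelope(2 * sin(2 * pi * 6 * t))
  central <- seq(round(length(t) * 0.1), round(length(t) * 0.9))
  expect_true(all(abs(env[central] - 2) < 0.02))
  expect_equal(amplitude_envelope(numeric(100)), numeric(100))
  # amplitude-modulated tone: envelope ~ modulator
  modu <- 1 + 0.5 * sin(2 * pi * 0.3 * t)
  env2 <- amplitude_envelope(modu * sin(2 * pi * 6 * t))
  rmse <- sqrt(mean((env2[central] - modu[central])^2))
  expect_lt(rmse / mean(modu), 0.02)
})

test_that("envelope smoothing uses the band-scaled sigma and preserves means", {
  p <- detection_params()
  expect_equal(0.25 / theta$f_center + 0.25 / theta$bandwidth, 0.1041667,
               tolerance = 1e-6)
  const <- smooth_envelope(rep(3, 1000), theta, fs, p)
  expect_equal(const, rep(3, 1000), tolerance = 1e-9)
  x <- make_random_envelope(5000, seed = 2)
  expect_equal(mean(smooth_envelope(x, theta, fs, p)), mean(x),
               tolerance = 1e-3)
  # impulse response ~ discretized Gaussian
  imp <- numeric(2001)
  imp[1001] <- 1
  sm <- smooth_envelope(imp, theta, fs, p)
  sig_samp <- 0.1041667 * fs
  ref <- dnorm(seq(-1000, 1000), sd = sig_samp)
  ref <- ref / sum(ref)
  expect_lt(max(abs(sm - ref)), 1e-5)
})

test_that("dual-threshold detection handles canonical cases", {
  p <- detection_params()
  expect_equal(nrow(detect_events(rep(1, 5000), theta, fs, p)), 0)
  # one clear 4 s half-sine bump: 4 s x 6 Hz = 24 >= 16 cycles
  n <- 30 * fs
  env <- rep(0.1, n)
  bump <- seq(10 * fs, 14 * fs)
  env[bump] <- 0.1 + 2 * sin(pi * seq_along(bump) / length(bump))
  ev <- detect_events(env, theta, fs, p)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$start_s - 10), 0.2)
  expect_lt(abs(ev$end_s - 14), 0.2)
  expect_gte(ev$n_cycles, 16)
})

test_that("sub-threshold gaps merge within the band allowance only", {
  p <- detection_params()
  n <- 40 * fs
  mk <- function(gap_s) {
    env <- rep(0.1, n)
    b1 <- seq(10 * fs, 13 * fs)
    b2 <- seq((13 + gap_s) * fs, (16 + gap_s) * fs)
    env[b1] <- 0.1 + 2 * sin(pi * seq_along(b1) / length(b1))
    env[b2] <- 0.1 + 2 * sin(pi * seq_along(b2) / length(b2))
    env
  }
  # theta gap allowance = 4 / 6 = 0.667 s
  expect_equal(nrow(detect_events(mk(0.3), theta, fs, p)), 1)
  expect_equal(nrow(detect_events(mk(1.0), theta, fs, p)), 2)
})

test_that("detection equals the brute-force oracle on random envelopes", {
  p <- detection_params()
  for (s in 1:25) {
    env <- make_random_envelope(8000, seed = s)
    got <- detect_events(env, theta, fs, p)
    want <- oracle_detect_events(env, theta, fs, p)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(got$start_s, (want$first - 1) / fs)
      expect_equal(got$end_s, want$last / fs)
    }
  }
})

test_that("detections are scale invariant, ordered, in-range and non-overlapping", {
  p <- detection_params()
  env <- make_random_envelope(10000, seed = 77)
  base <- detect_events(env, theta, fs, p)
  for (c0 in c(0.01, 3, 1e4)) {
    scaled <- detect_events(c0 * env, theta, fs, p)
    expect_equal(scaled$start_s, base$start_s)
    expect_equal(scaled$end_s, base$end_s)
  }
  if (nrow(base) > 1) {
    expect_true(all(diff(base$start_s) > 0))
    expect_true(all(base$start_s[-1] >= base$end_s[-nrow(base)]))
  }
  expect_true(all(base$start_s >= 0 & base$end_s <= 10000 / fs))
})

test_that("raising the cycle requirement never adds events", {
  p <- detection_params()
  for (s in 1:10) {
    env <- make_random_envelope(6000, seed = 100 + s)
    counts <- vapply(c(4, 8, 16, 32), function(mc) {
      b <- frequency_band("theta", 4, 8, mc, 4)
      nrow(detect_events(env, b, fs, p))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("spectral annotation localizes an injected 2.5 Hz (delta) modulation", {
  # longer bursts so delta events can span their 8-cycle (3.2 s) minimum
  cfg <- spike_sim_config(duration = 120, nested_freq = 2.5, seed = 21,
                          nb_duration_mean = 4, nb_min_ibi = 4.5)
  sig <- population_signal(simulate_well(cfg))
  ev <- detect_all_bands(sig)
  expect_gt(sum(ev$band == "delta"), 0)
  ann <- event_spectra(sig, ev[ev$band == "delta", , drop = FALSE])
  pf <- ann$peak_freq_hz[!is.na(ann$peak_freq_hz)]
  expect_gt(length(pf), 0)
  expect_gte(mean(abs(pf - 2.5) <= 0.5), 0.9)
})
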