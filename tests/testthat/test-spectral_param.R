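test_that("Welch PSD localizes tones and satisfies Parseval on noise", {
  fs <- 500
  t <- seq(0, 8 - 1 / fs, by = 1 / fs)
  w <- welch_psd(sin(2 * pi * 5 * t), fs)
  expect_equal(w$freqs[which.max(w$psd)], 5, tolerance = 0.26)
  expect_true(all(w$freqs >= 0.05 & w$freqs <= 40))
  x <- withr::with_seed(3, rnorm(40000, sd = 2))
  full <- welch_psd(x, fs, welch_params(f_min = 0, f_max = fs / 2))
  df <- full$freqs[2] - full$freqs[1]
  expect_lt(abs(sum(full$psd) * df / var(x) - 1), 0.05)
})

test_that("Welch segments shorten for brief events", {
  fs <- 500
  x <- withr::with_seed(4, rnorm(1.5 * fs))  # a 1.5 s event
  w <- welch_psd(x, fs)
  # effective segment = 1.5 s -> frequency resolution 1/1.5 Hz
  expect_equal(w$freqs[2] - w$freqs[1], 1 / 1.5, tolerance = 1e-9)
})

test_that("aperiodic fit is exact on an exact power law", {
  ps <- simulate_psd(psd_sim_config(offset = 2, exponent = 1.5, noise_sd = 0))
  fit <- fit_spectrum(ps$freqs, ps$psd)
  expect_equal(fit$offset, 2, tolerance = 1e-6)
  expect_equal(fit$exponent, 1.5, tolerance = 1e-6)
  expect_equal(nrow(fit$peaks), 0)
  expect_error(fit_spectrum(1:20, rep(0, 20)), "positive")
})

test_that("a single synthetic peak is recovered accurately", {
  ps <- simulate_psd(psd_sim_config(offset = 2, exponent = 1.5,
                                    peaks = list(c(6, 0.5, 2)), noise_sd = 0))
  fit <- fit_spectrum(ps$freqs, ps$psd)
  expect_equal(nrow(fit$peaks), 1)
  expect_lt(abs(fit$peaks$center - 6), 0.1)
  expect_lt(abs(fit$peaks$height - 0.5), 0.05)
  expect_lt(abs(fit$offset - 2), 0.05)
  expect_lt(abs(fit$exponent - 1.5), 0.05)
  # model reconstruction: flattened + aperiodic = log psd - residual ~ log psd
  expect_lt(max(abs(fit$flattened +
                      (fit$offset - fit$exponent * log10(fit$freqs)) -
                      fit$log_psd)), 1e-9)
})

test_that("rescaling power shifts the offset only", {
  ps <- simulate_psd(psd_sim_config(offset = 1, exponent = 1.2,
                                    peaks = list(c(8, 0.4, 3)),
                                    noise_sd = 0.03, seed = 6))
  f1 <- fit_spectrum(ps$freqs, ps$psd)
  f2 <- fit_spectrum(ps$freqs, 100 * ps$psd)
  expect_equal(f2$offset - f1$offset, 2, tolerance = 1e-6)
  expect_equal(f2$exponent, f1$exponent, tolerance = 1e-6)
  expect_equal(f2$peaks$center, f1$peaks$center, tolerance = 1e-4)
})

test_that("peak count and widths respect the settings", {
  st <- specfit_settings(max_n_peaks = 2)
  ps <- simulate_psd(psd_sim_config(
    offset = 1.5, exponent = 1, noise_sd = 0.05, seed = 12,
    peaks = list(c(3, 0.6, 2), c(7, 0.5, 2), c(11, 0.6, 2))))
  fit <- fit_spectrum(ps$freqs, ps$psd, st)
  expect_lte(nrow(fit$peaks), 2)
  if (nrow(fit$peaks) > 0) {
    expect_true(all(fit$peaks$bandwidth >= st$peak_width_limits[1] - 1e-9))
    expect_true(all(fit$peaks$bandwidth <= st$peak_width_limits[2] + 1e-9))
  }
})

test_that("band peaks read the flattened maximum with documented tie-breaks", {
  theta <- default_bands()$theta
  ps <- simulate_psd(psd_sim_config(offset = 2, exponent = 1.5,
                                    peaks = list(c(5.25, 0.4, 2)),
                                    noise_sd = 0))
  fit <- fit_spectrum(ps$freqs, ps$psd)
  bp <- band_peak(fit, theta)
  expect_equal(bp$band, "theta")
  expect_lt(abs(bp$peak_freq - 5.25), 0.26)
  expect_gt(bp$peak_power, 0.3)
  # strictly negative flattened spectrum in band -> absent
  fit2 <- fit_spectrum(ps$freqs, ps$psd)
  fit2$flattened <- fit2$flattened - 10
  expect_null(band_peak(fit2, theta))
  # exact tie resolves to the lower frequency
  fit3 <- fit2
  fit3$flattened[match(c(5, 7), fit3$freqs)] <- 11
  expect_equal(band_peak(fit3, theta)$peak_freq, 5)
  expect_error(band_peak(fit, frequency_band("hf", 60, 80, 1, 1)), "cover")
})

test_that("only events of at least one second get spectral annotations", {
  cfg <- spike_sim_config(duration = 60, seed = 31)
  sig <- population_signal(simulate_well(cfg))
  ev <- data.frame(well_id = "w", band = "theta",
                   start_s = c(5, 20), end_s = c(5.9, 24),
                   duration_s = c(0.9, 4), n_cycles = c(5.4, 24),
                   peak_envelope = c(1, 2))
  ann <- event_spectra(sig, ev)
  expect_true(is.na(ann$offset[1]) && is.na(ann$peak_freq_hz[1]))
  expect_false(is.na(ann$offset[2]))
})
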