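test_that("spike simulator is a pure function of its config", {
  a <- simulate_well(spike_sim_config(duration = 20, seed = 3))
  b <- simulate_well(spike_sim_config(duration = 20, seed = 3))
  d <- simulate_well(spike_sim_config(duration = 20, seed = 4))
  expect_identical(a$electrode_spikes, b$electrode_spikes)
  expect_false(identical(a$electrode_spikes, d$electrode_spikes))
})

test_that("zero-rate configs give an empty recording", {
  rec <- simulate_well(spike_sim_config(duration = 10, nb_rate = 0,
                                        baseline_rate = 0, seed = 1))
  expect_equal(n_spikes(rec), 0)
})

test_that("spike counts agree with the integrated rate function", {
  # with no refractory deletion the count is exactly Poisson with mean equal
  # to the integrated rate: z-test at 3 SD per seed
  for (s in 1:5) {
    rec <- simulate_well(spike_sim_config(duration = 60, refractory = 0,
                                          seed = s))
    mu <- expected_spike_count(rec)
    expect_lt(abs(n_spikes(rec) - mu), 3 * sqrt(mu))
  }
  # refractory thinning only removes spikes (~5% at these in-burst rates)
  with_rp <- simulate_well(spike_sim_config(duration = 60, seed = 1))
  no_rp <- simulate_well(spike_sim_config(duration = 60, refractory = 0,
                                          seed = 1))
  expect_lte(n_spikes(with_rp), n_spikes(no_rp))
  expect_gt(n_spikes(with_rp), 0.9 * n_spikes(no_rp))
})

test_that("all simulated spikes lie in-range, sorted, and respect refractoriness", {
  cfg <- spike_sim_config(duration = 30, seed = 11, refractory = 0.002)
  rec <- simulate_well(cfg)
  for (st in rec$electrode_spikes) {
    expect_true(all(st >= 0 & st < 30))
    expect_true(!is.unsorted(st))
    if (length(st) > 1) expect_true(all(diff(st) >= 0.002))
  }
})

test_that("invalid spike configs are rejected", {
  expect_error(spike_sim_config(modulation_depth = 1.5), "modulation_depth")
  expect_error(spike_sim_config(baseline_rate = -1), ">= 0")
  expect_error(spike_sim_config(duration = Inf), "finite")
})

test_that("synthetic spectra follow the generative formula exactly", {
  ps <- simulate_psd(psd_sim_config(offset = 2, exponent = 1.5,
                                    freq_range = c(1, 40),
                                    freq_resolution = 1, noise_sd = 0))
  expect_equal(ps$psd[ps$freqs == 1], 100)
  expect_equal(ps$psd[ps$freqs == 10], 10^0.5)
  withpk <- simulate_psd(psd_sim_config(offset = 2, exponent = 1.5,
                                        peaks = list(c(6, 0.5, 2)),
                                        freq_range = c(1, 40),
                                        freq_resolution = 1, noise_sd = 0))
  expect_equal(log10(withpk$psd[withpk$freqs == 6]) -
                 log10(ps$psd[ps$freqs == 6]), 0.5)
  n1 <- simulate_psd(psd_sim_config(noise_sd = 0.1, seed = 5))
  n2 <- simulate_psd(psd_sim_config(noise_sd = 0.1, seed = 5))
  expect_identical(n1$psd, n2$psd)
  expect_error(psd_sim_config(peaks = list(c(100, 0.5, 2))), "freq_range")
})

test_that("occurrence generator respects bounds and its null case", {
  occ <- simulate_occurrence(occurrence_sim_config(seed = 2))
  expect_true(all(occ$n_oscillating >= 0 & occ$n_oscillating <= occ$n_wells))
  expect_false(any(duplicated(paste(occ$plate_id, occ$week))))
  # beta = 0, no plate effect: pooled fraction ~ Binomial(N, 0.5)
  null_occ <- simulate_occurrence(
    occurrence_sim_config(beta = rep(0, 6), plate_sd = 0,
                          n_plates_per_condition = 30,
                          wells_per_plate = 10, seed = 8))
  frac <- sum(null_occ$n_oscillating) / sum(null_occ$n_wells)
  n_tot <- sum(null_occ$n_wells)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n_tot))
})

test_that("a strong week effect makes occurrence rise monotonically", {
  occ <- simulate_occurrence(
    occurrence_sim_config(beta = c(0, 2, 0, 0, 0, 0), plate_sd = 0,
                          n_plates_per_condition = 40,
                          wells_per_plate = 12, seed = 9))
  by_week <- tapply(occ$n_oscillating / occ$n_wells, occ$week, mean)
  expect_true(all(diff(by_week) > 0))
})
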