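test_that("active-electrode criterion is >= 5 spikes per minute", {
  spikes <- list(A = seq_len(25) / 25 * 299, B = seq_len(24) / 24 * 299,
                 C = numeric(0))
  rec <- well_recording(spikes, duration = 300)
  expect_equal(active_electrodes(rec), "A")  # 25/300 s = 5/min exactly
})

test_that("ISI burst detection matches its definition and oracle", {
  st <- seq(0, by = 0.05, length.out = 6)
  b <- detect_bursts_isi(st)
  expect_equal(nrow(b), 1)
  expect_equal(b$n_spikes, 6)
  expect_equal(c(b$start, b$end), c(0, 0.25))
  expect_equal(nrow(detect_bursts_isi(seq(0, by = 0.05, length.out = 4))), 0)
  for (s in 1:40) {
    train <- make_poisson_train(rate = 8, duration = 30, seed = s)
    expect_equal(detect_bursts_isi(train),
                 oracle_bursts_isi(train, 5, 0.1),
                 ignore_attr = TRUE)
  }
})

test_that("Poisson surprise matches an independent tail computation", {
  # planted cluster: 20 spikes in 0.1 s on a 1 Hz/300 s background
  bg <- make_poisson_train(1, 300, seed = 2)
  burst <- 150 + sort(withr::with_seed(3, runif(20, 0, 0.1)))
  st <- sort(c(bg, burst))
  found <- detect_bursts_surprise(st, 300)
  expect_equal(nrow(found), 1)
  expect_gte(found$n_spikes, 18)
  expect_gte(found$surprise, 5)
  # independent check: log10 upper tail via the gamma-Poisson identity
  lambda <- length(st) / 300
  mu <- lambda * (found$end - found$start)
  tail_log10 <- pgamma(mu, shape = found$n_spikes - 2, lower.tail = TRUE,
                       log.p = TRUE) / log(10)
  expect_equal(found$surprise, -tail_log10, tolerance = 1e-8)
})

test_that("surprise detection is specific on regular and Poisson trains", {
  expect_equal(nrow(detect_bursts_surprise(seq(0, 300, by = 1), 300)), 0)
  fp <- vapply(1:20, function(s) {
    nrow(detect_bursts_surprise(make_poisson_train(1, 300, seed = s), 300))
  }, numeric(1))
  expect_gte(mean(fp == 0), 0.95)
})

test_that("planted bursts are always detected across backgrounds", {
  hits <- vapply(1:10, function(s) {
    bg <- make_poisson_train(1, 300, seed = 100 + s)
    burst <- 100 + sort(withr::with_seed(200 + s, runif(20, 0, 0.1)))
    found <- detect_bursts_surprise(sort(c(bg, burst)), 300)
    nrow(found) >= 1 && any(found$surprise >= 5 & found$n_spikes >= 18)
  }, logical(1))
  expect_true(all(hits))
})

test_that("pooled-train network bursts respect the electrode fraction", {
  # 16 electrodes all active over 60 s; a 12-spike cluster at 5 ms spacing
  base <- lapply(1:16, function(i) seq(5 + i * 0.35, by = 10, length.out = 5))
  names(base) <- sprintf("E%02d", 1:16)
  cluster <- seq(30, by = 0.005, length.out = 12)
  spread <- base
  for (k in 1:12) {
    e <- sprintf("E%02d", ((k - 1) %% 8) + 1)  # 8 distinct electrodes
    spread[[e]] <- sort(c(spread[[e]], cluster[k]))
  }
  rec <- well_recording(spread, duration = 60)
  nb <- detect_network_bursts_isi(rec)
  expect_equal(nrow(nb), 1)
  expect_gte(nb$n_spikes, 12)
  expect_gte(nb$n_electrodes, 8)
  one <- base
  one$E01 <- sort(c(one$E01, cluster))
  rec1 <- well_recording(one, duration = 60)
  expect_equal(nrow(detect_network_bursts_isi(rec1)), 0)  # 1/16 < 25%
})

test_that("pooled network-burst detection matches the brute-force oracle", {
  for (s in 1:20) {
    cfg <- spike_sim_config(n_electrodes = 8, duration = 30, seed = 300 + s,
                            burst_peak_rate = 25)
    rec <- simulate_well(cfg)
    got <- detect_network_bursts_isi(rec)
    want <- oracle_nb_isi(rec)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$n_electrodes, want$n_electrodes)
  }
})

test_that("envelope network bursts recover injected bursts and merge close ones", {
  hit <- vapply(1:8, function(s) {
    cfg <- spike_sim_config(seed = s, duration = 120, nb_rate = 0.12,
                            nb_min_ibi = 3, nb_duration_mean = 1.0,
                            modulation_depth = 0)
    rec <- simulate_well(cfg)
    nrow(detect_network_bursts_envelope(rec)) /
      length(rec$metadata$injected$nb_onsets)
  }, numeric(1))
  expect_true(all(abs(hit - 1) <= 0.1))
  # stationary background at a typical culture firing rate: no network bursts
  fp <- vapply(1:10, function(s) {
    rec <- simulate_well(spike_sim_config(seed = 400 + s, duration = 120,
                                          nb_rate = 0, baseline_rate = 10))
    nrow(detect_network_bursts_envelope(rec))
  }, numeric(1))
  expect_gte(mean(fp == 0), 0.9)
})

test_that("network bursts closer than the minimum IBI merge", {
  # two dense clusters 0.5 s apart on 4 electrodes
  mk <- function(t0) seq(t0, t0 + 0.4, by = 0.01)
  spikes <- list(A = sort(c(mk(10), mk(10.9), seq(1, 59, 2))),
                 B = sort(c(mk(10), mk(10.9), seq(1.2, 59, 2))),
                 C = sort(c(mk(10), mk(10.9), seq(1.4, 59, 2))),
                 D = sort(c(mk(10), mk(10.9), seq(1.6, 59, 2))))
  rec <- well_recording(spikes, duration = 60)
  nb <- detect_network_bursts_envelope(rec)
  expect_equal(nrow(nb), 1)
  expect_lt(nb$start, 10.1)
  expect_gt(nb$end, 11.2)
})

test_that("synchrony index separates co-firing from independence", {
  tr <- make_poisson_train(0.02, 300, seed = 5)  # sparse: 1-s window ~ empty
  rec_same <- well_recording(list(A = tr, B = tr), duration = 300)
  expect_gt(synchrony_index(rec_same, min_rate = 0.5), 0.9)
  a <- make_poisson_train(5, 300, seed = 6)
  b <- make_poisson_train(5, 300, seed = 7)
  rec_ind <- well_recording(list(A = a, B = b), duration = 300)
  expect_lt(abs(synchrony_index(rec_ind) - 0.02), 0.01)
  expect_error(synchrony_index(well_recording(list(A = tr), 300)), "2 active")
})

test_that("jitter only decreases synchrony, on average", {
  base <- make_poisson_train(4, 300, seed = 8)
  mean_sync <- function(sd_jit) {
    mean(vapply(1:8, function(s) {
      b <- withr::with_seed(s, sort(pmin(pmax(base + rnorm(length(base),
                                                           0, sd_jit), 0), 299.999)))
      synchrony_index(well_recording(list(A = base, B = b), 300))
    }, numeric(1)))
  }
  vals <- c(mean_sync(0.005), mean_sync(0.05), mean_sync(0.5))
  expect_true(all(diff(vals) < 0))
})
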