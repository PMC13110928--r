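# Independent brute-force oracles, written as direct transcriptions of the
# detector definitions (plain loops, no shared code with the implementations).

# Dual-threshold oscillation detector: direct sample-by-sample scan.
oracle_detect_events <- function(smoothed, band, fs, params = detection_params()) {
  lo <- stats::quantile(smoothed, params$low_percentile / 100, names = FALSE)
  hi <- stats::quantile(smoothed, params$high_percentile / 100, names = FALSE)
  n <- length(smoothed)
  # collect maximal runs strictly above lo
  cand <- list()
  i <- 1
  while (i <= n) {
    if (smoothed[i] > lo) {
      j <- i
      while (j < n && smoothed[j + 1] > lo) j <- j + 1
      cand[[length(cand) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  if (length(cand) == 0) return(data.frame(first = integer(0), last = integer(0)))
  # merge across short gaps
  max_gap <- band$gap_allowance_cycles / band$f_center * fs
  merged <- list(cand[[1]])
  if (length(cand) > 1) {
    for (k in 2:length(cand)) {
      prev <- merged[[length(merged)]]
      gap <- cand[[k]][1] - prev[2] - 1
      if (gap <= max_gap) merged[[length(merged)]] <- c(prev[1], cand[[k]][2])
      else merged[[length(merged) + 1]] <- cand[[k]]
    }
  }
  # high-threshold and minimum-cycle acceptance
  keep <- list()
  for (m in merged) {
    seg <- smoothed[m[1]:m[2]]
    dur <- (m[2] - m[1] + 1) / fs
    if (max(seg) > hi && dur * band$f_center >= band$min_cycles)
      keep[[length(keep) + 1]] <- m
  }
  if (length(keep) == 0) return(data.frame(first = integer(0), last = integer(0)))
  data.frame(first = vapply(keep, `[`, numeric(1), 1),
             last = vapply(keep, `[`, numeric(1), 2))
}

# ISI burst detector: try every possible start, grow while ISIs are small.
oracle_bursts_isi <- function(times, min_spikes = 5, max_isi = 0.1) {
  n <- length(times)
  res <- list()
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && times[j + 1] - times[j] <= max_isi) j <- j + 1
    if (j - i + 1 >= min_spikes)
      res[[length(res) + 1]] <- c(times[i], times[j], j - i + 1)
    i <- j + 1
  }
  if (length(res) == 0)
    return(data.frame(start = numeric(0), end = numeric(0), n_spikes = integer(0)))
  m <- do.call(rbind, res)
  data.frame(start = m[, 1], end = m[, 2], n_spikes = as.integer(m[, 3]))
}

# Pooled-train network-burst detector oracle.
oracle_nb_isi <- function(recording, min_spikes = 10, max_isi = 0.010,
                          min_electrode_frac = 0.25, min_rate = 5) {
  act <- c()
  for (e in names(recording$electrode_spikes)) {
    if (length(recording$electrode_spikes[[e]]) / (recording$duration / 60) >= min_rate)
      act <- c(act, e)
  }
  tt <- c(); ee <- c()
  for (e in act) {
    tt <- c(tt, recording$electrode_spikes[[e]])
    ee <- c(ee, rep(e, length(recording$electrode_spikes[[e]])))
  }
  o <- order(tt, ee)
  tt <- tt[o]; ee <- ee[o]
  runs <- oracle_bursts_isi(tt, min_spikes, max_isi)
  keep <- logical(nrow(runs))
  nel <- integer(nrow(runs))
  for (r in seq_len(nrow(runs))) {
    sel <- tt >= runs$start[r] & tt <= runs$end[r]
    nel[r] <- length(unique(ee[sel]))
    keep[r] <- nel[r] / length(act) >= min_electrode_frac
  }
  cbind(runs[keep, , drop = FALSE], n_electrodes = nel[keep])
}

# Poisson train on [0, duration] at the given rate.
make_poisson_train <- function(rate, duration, seed) {
  withr::with_seed(seed, sort(stats::runif(stats::rpois(1, rate * duration),
                                           0, duration)))
}

# A noise envelope with occasional smooth bumps, for detector fuzzing.
make_random_envelope <- function(n, seed, fs = 500) {
  withr::with_seed(seed, {
    base <- abs(stats::rnorm(n, 1, 0.3))
    nb <- sample(0:4, 1)
    t <- seq_len(n)
    for (k in seq_len(nb)) {
      c0 <- stats::runif(1, 1, n)
      w <- stats::runif(1, 0.2, 3) * fs
      base <- base + stats::runif(1, 0.5, 4) * exp(-(t - c0)^2 / (2 * w^2))
    }
    base
  })
}
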