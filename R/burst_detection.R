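#' Active electrodes of a recording
#'
#' An electrode is active when its mean firing rate reaches `min_rate`
#' spikes per minute (inclusive).
#'
#' @param recording a [well_recording()].
#' @param min_rate threshold, spikes/minute (default 5).
#' @return character vector of active electrode ids.
#' @export
active_electrodes <- function(recording, min_rate = 5) {
  if (recording$duration <= 0) stop("duration must be positive")
  rates <- vapply(recording$electrode_spikes, length, integer(1)) /
    (recording$duration / 60)
  names(rates)[rates >= min_rate]
}

#' ISI-threshold burst detection on one spike train
#'
#' A burst is a maximal run of consecutive spikes in which every interspike
#' interval is at most `max_isi`, containing at least `min_spikes` spikes.
#'
#' @param spike_times sorted numeric spike times, seconds.
#' @param min_spikes minimum spikes per burst (default 5).
#' @param max_isi maximum within-burst ISI, seconds (default 0.100).
#' @return data.frame of bursts: `start, end, n_spikes` (start/end are the
#'   first/last spike times).
#' @export
detect_bursts_isi <- function(spike_times, min_spikes = 5, max_isi = 0.100) {
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_spikes = integer(0))
  n <- length(spike_times)
  if (n < min_spikes) return(empty)
  ok <- diff(spike_times) <= max_isi
  runs <- run_bounds(ok)
  if (nrow(runs) == 0) return(empty)
  # a run of k consecutive small ISIs spans k+1 spikes
  n_sp <- runs$last - runs$first + 2L
  keep <- n_sp >= min_spikes
  runs <- runs[keep, , drop = FALSE]
  if (nrow(runs) == 0) return(empty)
  data.frame(start = spike_times[runs$first],
             end = spike_times[runs$last + 1L],
             n_spikes = n_sp[keep])
}

# Poisson surprise of a burst of n spikes spanning T seconds under rate
# lambda. The span is delimited by its first and last spike, so those two are
# certain given the candidate; scoring the n - 2 interior spikes against the
# Poisson count law removes that selection bias (a bare pair has S = 0):
# S = -log10 P(N >= n - 2), N ~ Poisson(lambda * T).
# Base 10 makes the default acceptance S >= 5 mean P <= 1e-5, stringent
# enough that background Poisson firing is essentially never called a burst
# even though the detector scans many candidate windows.
poisson_surprise <- function(n, T, lambda) {
  -stats::ppois(n - 3, lambda * T, lower.tail = FALSE, log.p = TRUE) / log(10)
}

#' Poisson-surprise burst detection (Legendy-Salcman)
#'
#' Scores candidate spike clusters by the surprise statistic: the burst span
#' `T` runs from the cluster's first to last spike, and
#' `S = -log10 P(>= n - 2 spikes in T | Poisson at the train's mean rate)` --
#' the two span-delimiting spikes are conditioned on, so only the interior
#' spike count is scored (an isolated close pair is never surprising), and
#' the decimal log makes the default threshold `S >= 5` correspond to a tail
#' probability of 1e-5, so stationary background firing is essentially never
#' called a burst despite the many candidate windows scanned.
#' Candidates are seeded at runs of interspike intervals below half the mean
#' ISI, greedily extended spike-by-spike at the right edge and trimmed at the
#' left edge while `S` increases, and accepted when `S >= min_surprise`.
#' Accepted bursts never overlap.
#'
#' @param spike_times sorted numeric spike times, seconds.
#' @param duration recording duration, seconds (sets the null rate
#'   `length(spike_times) / duration`).
#' @param min_surprise acceptance threshold (default 5, decimal-log units).
#' @param min_spikes minimum spikes per candidate (default 3).
#' @return data.frame of bursts: `start, end, n_spikes, surprise`.
#' @export
detect_bursts_surprise <- function(spike_times, duration, min_surprise = 5,
                                   min_spikes = 3) {
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_spikes = integer(0), surprise = numeric(0))
  n <- length(spike_times)
  if (duration <= 0) stop("duration must be positive")
  if (n < max(2, min_spikes)) return(empty)
  lambda <- n / duration
  isi <- diff(spike_times)
  mean_isi <- mean(isi)
  seeds <- run_bounds(isi < mean_isi / 2)
  if (nrow(seeds) == 0) return(empty)
  s_of <- function(i, j) {
    poisson_surprise(j - i + 1, spike_times[j] - spike_times[i], lambda)
  }
  out <- list()
  last_end <- 0L
  for (r in seq_len(nrow(seeds))) {
    i <- seeds$first[r]           # first spike of the candidate
    j <- seeds$last[r] + 1L       # last spike of the candidate
    if (j - i + 1L < min_spikes) next
    if (i <= last_end) i <- last_end + 1L
    if (j - i + 1L < min_spikes) next
    s <- s_of(i, j)
    # extend right while surprise increases
    while (j < n) {
      s2 <- s_of(i, j + 1L)
      if (s2 > s) {
        j <- j + 1L
        s <- s2
      } else break
    }
    # trim left while surprise increases
    while (j - i + 1L > min_spikes) {
      s2 <- s_of(i + 1L, j)
      if (s2 > s) {
        i <- i + 1L
        s <- s2
      } else break
    }
    if (s >= min_surprise) {
      out[[length(out) + 1L]] <-
        data.frame(start = spike_times[i], end = spike_times[j],
                   n_spikes = j - i + 1L, surprise = s)
      last_end <- j
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' ISI-threshold network-burst detection
#'
#' Pools the spike trains of all active electrodes (ties in time broken by
#' electrode id), finds maximal runs of pooled interspike intervals at most
#' `max_isi` with at least `min_spikes` spikes, and keeps runs whose spikes
#' span at least `min_electrode_frac` of the active electrodes.
#'
#' @param recording a [well_recording()].
#' @param min_spikes minimum pooled spikes per network burst (default 10).
#' @param max_isi maximum pooled ISI, seconds (default 0.010).
#' @param min_electrode_frac minimum participating fraction of active
#'   electrodes (default 0.25).
#' @param min_rate active-electrode criterion, spikes/minute.
#' @return data.frame of network bursts: `start, end, n_spikes,
#'   n_electrodes`, plus a `participating` list-column of electrode ids.
#' @export
detect_network_bursts_isi <- function(recording, min_spikes = 10,
                                      max_isi = 0.010,
                                      min_electrode_frac = 0.25,
                                      min_rate = 5) {
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_spikes = integer(0), n_electrodes = integer(0))
  act <- active_electrodes(recording, min_rate)
  if (length(act) == 0) return(empty)
  pool <- pooled_spikes(recording, act)
  if (nrow(pool) < min_spikes) return(empty)
  ok <- diff(pool$time) <= max_isi
  runs <- run_bounds(ok)
  if (nrow(runs) == 0) return(empty)
  rows <- list()
  for (r in seq_len(nrow(runs))) {
    i <- runs$first[r]
    j <- runs$last[r] + 1L
    if (j - i + 1L < min_spikes) next
    elec <- unique(pool$electrode[i:j])
    if (length(elec) / length(act) < min_electrode_frac) next
    rows[[length(rows) + 1L]] <-
      data.frame(start = pool$time[i], end = pool$time[j],
                 n_spikes = j - i + 1L, n_electrodes = length(elec))
    rows[[length(rows)]]$participating <- list(elec)
  }
  if (length(rows) == 0) return(empty)
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Envelope-threshold network-burst detection
#'
#' Builds the well-wide firing-rate envelope (10 ms bins over the active
#' electrodes' pooled spikes, Gaussian-smoothed), marks candidate regions
#' where the envelope exceeds `threshold_factor` times the recording-mean
#' rate, merges candidates separated by less than `min_ibi`, then expands
#' each candidate's boundaries symmetrically until it contains at least
#' `burst_inclusion` of the spikes in its local neighbourhood (the merged
#' region extended by `min_ibi / 2` on each side). Candidates must recruit
#' at least `min_electrode_frac` of the active electrodes.
#'
#' The vendor definitions of the envelope and the "burst inclusion" rule are
#' proprietary; this implementation is an explicit, documented approximation.
#'
#' @param recording a [well_recording()].
#' @param threshold_factor multiple of the mean rate defining candidates
#'   (default 2).
#' @param min_ibi minimum inter-burst interval, seconds (default 1.0);
#'   candidates closer than this are merged.
#' @param min_electrode_frac minimum participating fraction of active
#'   electrodes (default 0.25).
#' @param burst_inclusion fraction of neighbourhood spikes the reported burst
#'   must contain (default 0.75).
#' @param smoothing Gaussian smoothing sigma, seconds (default 0.1).
#' @param bin_width envelope bin width, seconds (default 0.010).
#' @param min_rate active-electrode criterion, spikes/minute.
#' @return data.frame of network bursts: `start, end, n_spikes,
#'   n_electrodes`.
#' @export
detect_network_bursts_envelope <- function(recording, threshold_factor = 2,
                                           min_ibi = 1.0,
                                           min_electrode_frac = 0.25,
                                           burst_inclusion = 0.75,
                                           smoothing = 0.1,
                                           bin_width = 0.010,
                                           min_rate = 5) {
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_spikes = integer(0), n_electrodes = integer(0))
  act <- active_electrodes(recording, min_rate)
  if (length(act) == 0) return(empty)
  pool <- pooled_spikes(recording, act)
  if (nrow(pool) == 0) return(empty)
  n_bins <- as.integer(ceiling(recording$duration / bin_width))
  idx <- pmin(floor(pool$time / bin_width) + 1L, n_bins)
  rate <- tabulate(idx, nbins = n_bins) / bin_width
  sigma <- smoothing / bin_width
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  pad <- min(half, n_bins - 1)
  padded <- c(rev(rate[seq_len(pad) + 1]), rate, rev(rate[(n_bins - pad):(n_bins - 1)]))
  sm <- stats::convolve(padded, rev(k), type = "open")
  sm <- sm[(half + pad + 1):(half + pad + n_bins)]
  thr <- threshold_factor * mean(rate)
  runs <- run_bounds(sm > thr)
  if (nrow(runs) == 0) return(empty)
  runs <- merge_runs(runs, max_gap = min_ibi / bin_width)
  rows <- list()
  for (r in seq_len(nrow(runs))) {
    t0 <- (runs$first[r] - 1) * bin_width
    t1 <- runs$last[r] * bin_width
    # neighbourhood spikes that plausibly belong to this burst
    lo <- t0 - min_ibi / 2
    hi <- t1 + min_ibi / 2
    nb_spk <- pool$time >= lo & pool$time < hi
    target <- burst_inclusion * sum(nb_spk)
    inside <- function(a, b) sum(pool$time >= a & pool$time < b)
    a <- t0
    b <- t1
    step <- bin_width
    while (inside(a, b) < target && (a > lo || b < hi)) {
      a <- max(lo, a - step)
      b <- min(hi, b + step)
    }
    sel <- pool$time >= a & pool$time < b
    if (sum(sel) == 0) next
    elec <- unique(pool$electrode[sel])
    if (length(elec) / length(act) < min_electrode_frac) next
    rows[[length(rows) + 1L]] <-
      data.frame(start = a, end = b, n_spikes = sum(sel),
                 n_electrodes = length(elec))
  }
  if (length(rows) == 0) return(empty)
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Pairwise synchrony index
#'
#' For every pair of active electrodes, the fraction of cross-spike
#' intervals with `|dt| <= window` relative to those with `|dt| <= broad`
#' (the broad +/-1 s cross-correlogram support), averaged over pairs.
#' Identical trains give values near 1; independent stationary trains give
#' `window / broad` (0.02 at the defaults) in expectation.
#'
#' @param recording a [well_recording()].
#' @param window synchrony lag window, seconds (default 0.020).
#' @param broad normalization window, seconds (default 1.0).
#' @param min_rate active-electrode criterion, spikes/minute.
#' @return synchrony index in `[0, 1]`.
#' @export
synchrony_index <- function(recording, window = 0.020, broad = 1.0,
                            min_rate = 5) {
  act <- active_electrodes(recording, min_rate)
  if (length(act) < 2) stop("need at least 2 active electrodes")
  count_within <- function(a, b, w) {
    # number of (i, j) pairs with |a_i - b_j| <= w; both sorted
    hi <- findInterval(a + w, b)
    lo <- findInterval(a - w, b, left.open = TRUE)
    sum(hi - lo)
  }
  pairs <- utils::combn(act, 2)
  vals <- apply(pairs, 2, function(p) {
    a <- recording$electrode_spikes[[p[1]]]
    b <- recording$electrode_spikes[[p[2]]]
    denom <- count_within(a, b, broad)
    if (denom == 0) return(NA_real_)
    count_within(a, b, window) / denom
  })
  mean(vals, na.rm = TRUE)
}
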