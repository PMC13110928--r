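#' Configuration for the synthetic MEA well generator
#'
#' Defines the generative model for one simulated well: network bursts (NBs)
#' arrive as a hard-core renewal process (candidate Poisson onsets thinned to a
#' minimum inter-onset interval), each burst drives participating electrodes
#' with a half-sine firing-rate envelope, optionally rate-modulated by a
#' sinusoid at `nested_freq` (the nested oscillation), on top of homogeneous
#' Poisson background firing. Electrode spike trains are inhomogeneous Poisson
#' processes thinned to an absolute refractory period.
#'
#' The defaults emulate a mature, strongly oscillatory culture: ~3 s network
#' bursts recurring every ~6.4 s, each carrying a 5 Hz (theta) rate modulation
#' at depth 0.8, over 0.5 Hz/electrode background firing.
#'
#' @param n_electrodes electrodes per well (default 16).
#' @param duration recording length, seconds (default 300).
#' @param nb_rate intensity (events/s) of the candidate Poisson process of NB
#'   onsets before hard-core thinning; the realized mean inter-onset interval
#'   is `nb_min_ibi + 1/nb_rate`.
#' @param nb_duration_mean mean NB duration, seconds. Durations are drawn from
#'   a Gamma distribution with 10% coefficient of variation and truncated so
#'   consecutive bursts never overlap.
#' @param nb_min_ibi hard minimum between consecutive NB onsets, seconds.
#' @param baseline_rate background firing rate, spikes/s per electrode.
#' @param burst_peak_rate peak of the within-burst half-sine rate envelope,
#'   spikes/s per electrode.
#' @param nested_freq frequency of the nested rate modulation, Hz.
#' @param modulation_depth modulation depth in `[0, 1]`; 0 disables the nested
#'   oscillation (amplitude-matched surrogate bursts).
#' @param participation_prob probability that an electrode joins a given NB.
#' @param refractory absolute refractory period, seconds; spikes closer than
#'   this to their (kept) predecessor on one electrode are deleted. Default
#'   2 ms, the resolution of the downstream spike histogram.
#' @param seed integer seed; the generator is a pure function of its config.
#' @return object of class `spike_sim_config`.
#' @export
spike_sim_config <- function(n_electrodes = 16, duration = 300,
                             nb_rate = 0.35, nb_duration_mean = 3.0,
                             nb_min_ibi = 3.5, baseline_rate = 0.5,
                             burst_peak_rate = 40, nested_freq = 5,
                             modulation_depth = 0.8,
                             participation_prob = 0.9,
                             refractory = 0.002, seed = 1L) {
  cfg <- list(n_electrodes = n_electrodes, duration = duration,
              nb_rate = nb_rate, nb_duration_mean = nb_duration_mean,
              nb_min_ibi = nb_min_ibi, baseline_rate = baseline_rate,
              burst_peak_rate = burst_peak_rate, nested_freq = nested_freq,
              modulation_depth = modulation_depth,
              participation_prob = participation_prob,
              refractory = refractory, seed = as.integer(seed))
  num <- cfg[setdiff(names(cfg), "seed")]
  if (any(!vapply(num, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                  logical(1))))
    stop("all spike_sim_config values must be finite scalars")
  if (any(unlist(num[c("nb_rate", "baseline_rate", "burst_peak_rate",
                       "nb_duration_mean", "nb_min_ibi", "refractory")]) < 0))
    stop("rates, durations and refractory must be >= 0")
  if (cfg$modulation_depth < 0 || cfg$modulation_depth > 1)
    stop("modulation_depth must lie in [0, 1]")
  if (cfg$participation_prob < 0 || cfg$participation_prob > 1)
    stop("participation_prob must lie in [0, 1]")
  if (cfg$n_electrodes < 1 || cfg$duration <= 0)
    stop("need n_electrodes >= 1 and duration > 0")
  structure(cfg, class = "spike_sim_config")
}

# Hard-core renewal NB onsets: greedy thinning of a Poisson process with
# intensity nb_rate is equivalent, by memorylessness, to gaps of
# nb_min_ibi + Exp(nb_rate) after the first onset.
nb_onsets <- function(cfg) {
  if (cfg$nb_rate <= 0) return(numeric(0))
  onsets <- numeric(0)
  t <- stats::rexp(1, cfg$nb_rate)
  while (t < cfg$duration) {
    onsets <- c(onsets, t)
    t <- t + cfg$nb_min_ibi + stats::rexp(1, cfg$nb_rate)
  }
  onsets
}

# Burst half-sine envelope: peaks at burst_peak_rate mid-burst, zero at the
# edges (smooth onset/offset avoids filter ringing downstream).
burst_envelope <- function(t, onset, dur, peak) {
  u <- (t - onset) / dur
  ifelse(u > 0 & u < 1, peak * sin(pi * u), 0)
}

# Inhomogeneous Poisson spikes on [t0, t0+dur] by thinning at rate bound rmax.
rinhpois <- function(t0, dur, rate_fn, rmax) {
  n <- stats::rpois(1, rmax * dur)
  if (n == 0) return(numeric(0))
  cand <- sort(stats::runif(n, t0, t0 + dur))
  keep <- stats::runif(n) * rmax < rate_fn(cand)
  cand[keep]
}

# Delete spikes within `refractory` of their kept predecessor.
apply_refractory <- function(times, refractory) {
  if (length(times) < 2 || refractory <= 0) return(times)
  keep <- logical(length(times))
  keep[1] <- TRUE
  last <- times[1]
  for (i in 2:length(times)) {
    if (times[i] - last >= refractory) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}

#' Simulate one MEA well
#'
#' Draws network-burst onsets, per-burst durations and electrode
#' participation, then generates each electrode's spike train as an
#' inhomogeneous Poisson process whose rate is the background rate plus, for
#' participating electrodes, the burst half-sine envelope modulated by
#' `(1 + modulation_depth * sin(2 pi nested_freq (t - onset)))`.
#'
#' @param config a [spike_sim_config()].
#' @return a [well_recording()] with attributes `nb_onsets`, `nb_durations`
#'   (the injected ground truth) attached as `metadata$injected`.
#' @seealso [spike_sim_config()] for the generative model.
#' @export
simulate_well <- function(config) {
  stopifnot(inherits(config, "spike_sim_config"))
  cfg <- config
  withr::with_seed(cfg$seed, {
    onsets <- nb_onsets(cfg)
    ndur <- length(onsets)
    durs <- if (ndur > 0) {
      shape <- 100  # CV 10%
      d <- stats::rgamma(ndur, shape = shape, rate = shape / cfg$nb_duration_mean)
      # never let a burst run past the next onset (or the recording end)
      lim <- c(diff(onsets), cfg$duration - onsets[ndur])
      pmin(d, lim)
    } else numeric(0)
    participation <- if (ndur > 0) {
      matrix(stats::runif(cfg$n_electrodes * ndur) < cfg$participation_prob,
             nrow = cfg$n_electrodes)
    } else matrix(logical(0), nrow = cfg$n_electrodes)
    rmax <- cfg$baseline_rate +
      cfg$burst_peak_rate * (1 + cfg$modulation_depth)
    ids <- sprintf("E%02d", seq_len(cfg$n_electrodes))
    spikes <- vector("list", cfg$n_electrodes)
    for (e in seq_len(cfg$n_electrodes)) {
      bursts_e <- which(participation[e, ])
      rate_fn <- function(t) {
        r <- rep(cfg$baseline_rate, length(t))
        for (b in bursts_e) {
          env <- burst_envelope(t, onsets[b], durs[b], cfg$burst_peak_rate)
          inb <- env > 0
          if (any(inb)) {
            mod <- 1 + cfg$modulation_depth *
              sin(2 * pi * cfg$nested_freq * (t[inb] - onsets[b]))
            r[inb] <- r[inb] + env[inb] * mod
          }
        }
        r
      }
      st <- if (rmax > 0) rinhpois(0, cfg$duration, rate_fn, rmax) else numeric(0)
      st <- st[st < cfg$duration]
      spikes[[e]] <- apply_refractory(st, cfg$refractory)
    }
    names(spikes) <- ids
    well_recording(
      spikes, duration = cfg$duration,
      well_id = sprintf("sim%04d", cfg$seed),
      metadata = list(injected = list(nb_onsets = onsets, nb_durations = durs,
                                      participation = participation),
                      config = unclass(cfg))
    )
  })
}

#' Expected spike count of a simulated well
#'
#' Closed-form integral of the generative rate function given the injected
#' burst times (before refractory thinning): background plus, per
#' (electrode, burst) participation, the integral of the modulated half-sine
#' envelope.
#'
#' @param recording a [simulate_well()] output (needs `metadata$injected`).
#' @return expected total spike count (numeric).
#' @export
expected_spike_count <- function(recording) {
  inj <- recording$metadata$injected
  cfg <- recording$metadata$config
  if (is.null(inj) || is.null(cfg)) stop("recording carries no injected truth")
  base <- cfg$baseline_rate * cfg$duration * cfg$n_electrodes
  if (length(inj$nb_onsets) == 0) return(base)
  # integral over one burst of env(t) * (1 + m sin(2 pi f (t - onset)))
  per_burst <- vapply(seq_along(inj$nb_onsets), function(b) {
    d <- inj$nb_durations[b]
    f <- cfg$nested_freq
    m <- cfg$modulation_depth
    # int_0^d sin(pi t/d) dt = 2 d / pi
    i0 <- 2 * d / pi
    # int_0^d sin(pi t/d) sin(2 pi f t) dt, closed form (product-to-sum)
    a <- pi / d
    bb <- 2 * pi * f
    i1 <- if (abs(a - bb) < 1e-12) {
      d / 2  # degenerate case: envelope and modulation at the same frequency
    } else {
      (sin((a - bb) * d) / (a - bb) - sin((a + bb) * d) / (a + bb)) / 2
    }
    cfg$burst_peak_rate * (i0 + m * i1)
  }, numeric(1))
  base + sum(per_burst * colSums(inj$participation))
}

#' Configuration for the synthetic power-spectrum generator
#'
#' Generative twin of the spectral parameterization model: in log10 power,
#' `log10 psd(f) = offset - exponent * log10(f) + sum_k gaussian_k(f) + noise`,
#' with `gaussian_k` parameterized by (center frequency, height, bandwidth =
#' 2 sd).
#'
#' @param offset aperiodic offset, log10-power units.
#' @param exponent aperiodic exponent (power-law slope), >= 0.
#' @param peaks list of numeric triples `c(center_hz, height_log10, bandwidth_hz)`.
#' @param freq_range length-2 Hz range of the returned axis.
#' @param freq_resolution Hz spacing of the axis.
#' @param noise_sd SD of iid Gaussian noise added in log10 power.
#' @param seed integer seed.
#' @return object of class `psd_sim_config`.
#' @export
psd_sim_config <- function(offset = 1, exponent = 1.5, peaks = list(),
                           freq_range = c(0.5, 40), freq_resolution = 0.25,
                           noise_sd = 0, seed = 1L) {
  if (exponent < 0) stop("exponent must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(freq_range) != 2 || freq_range[1] <= 0 ||
      freq_range[1] >= freq_range[2])
    stop("freq_range must be an increasing positive pair")
  for (p in peaks) {
    if (length(p) != 3 || p[3] <= 0)
      stop("each peak must be c(center_hz, height, bandwidth>0)")
    if (p[1] < freq_range[1] || p[1] > freq_range[2])
      stop("peak centers must lie inside freq_range")
  }
  structure(list(offset = offset, exponent = exponent, peaks = peaks,
                 freq_range = freq_range, freq_resolution = freq_resolution,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "psd_sim_config")
}

#' Simulate a power spectrum with known parameters
#'
#' @param config a [psd_sim_config()].
#' @return list with `freqs` (Hz) and `psd` (linear power).
#' @export
simulate_psd <- function(config) {
  stopifnot(inherits(config, "psd_sim_config"))
  f <- seq(config$freq_range[1], config$freq_range[2],
           by = config$freq_resolution)
  logp <- config$offset - config$exponent * log10(f)
  for (p in config$peaks) {
    sd <- p[3] / 2
    logp <- logp + p[2] * exp(-(f - p[1])^2 / (2 * sd^2))
  }
  if (config$noise_sd > 0) {
    logp <- logp + withr::with_seed(config$seed,
                                    stats::rnorm(length(f), 0, config$noise_sd))
  }
  list(freqs = f, psd = 10^logp)
}

#' Configuration for the correlated well-occurrence generator
#'
#' Generative twin of the oscillation-emergence GEE: for plate i at week j,
#' the number of oscillating wells is
#' `k_ij ~ Binomial(n_ij, p_ij)` with
#' `logit(p_ij) = b0 + b1 t + b2 C80 + b3 C50 + b4 t*C80 + b5 t*C50 + u_i`,
#' `u_i ~ Normal(0, plate_sd^2)` a plate-level random intercept that induces
#' the within-plate correlation the exchangeable GEE targets. `t` is the
#' centered week.
#'
#' @param beta numeric length-6 coefficient vector (intercept, week, C80, C50,
#'   week:C80, week:C50) on the logit scale.
#' @param n_plates_per_condition plates per condition.
#' @param wells_per_plate integer count, or length-2 range sampled uniformly
#'   per plate.
#' @param weeks numeric vector of timepoints (weeks post-plating).
#' @param plate_sd SD of the plate random intercept, logit scale.
#' @param conditions condition labels; the first is the reference.
#' @param seed integer seed.
#' @return object of class `occurrence_sim_config`.
#' @export
occurrence_sim_config <- function(beta = c(-0.5, 0.8, 1.2, 0.6, 0.2, 0.1),
                                  n_plates_per_condition = 7,
                                  wells_per_plate = c(3, 18),
                                  weeks = 3:6, plate_sd = 0.5,
                                  conditions = c("iGluta", "80:20", "50:50"),
                                  seed = 1L) {
  beta <- as.numeric(unlist(beta))
  wells_per_plate <- as.numeric(unlist(wells_per_plate))
  weeks <- as.numeric(unlist(weeks))
  conditions <- as.character(unlist(conditions))
  if (length(beta) != 6) stop("beta must have length 6")
  if (plate_sd < 0) stop("plate_sd must be >= 0")
  if (length(weeks) < 1) stop("weeks must be non-empty")
  if (any(wells_per_plate < 1)) stop("wells_per_plate must be >= 1")
  if (length(conditions) != 3) stop("exactly three condition labels expected")
  structure(list(beta = as.numeric(beta),
                 n_plates_per_condition = as.integer(n_plates_per_condition),
                 wells_per_plate = wells_per_plate, weeks = as.numeric(weeks),
                 plate_sd = plate_sd, conditions = conditions,
                 seed = as.integer(seed)),
            class = "occurrence_sim_config")
}

#' Simulate a plate-level occurrence table
#'
#' @param config an [occurrence_sim_config()].
#' @return data.frame with columns `plate_id, condition, week, n_wells,
#'   n_oscillating` (one row per plate x week) and attribute `beta` (truth).
#' @export
simulate_occurrence <- function(config) {
  stopifnot(inherits(config, "occurrence_sim_config"))
  cfg <- config
  withr::with_seed(cfg$seed, {
    tc <- cfg$weeks - mean(cfg$weeks)
    rows <- list()
    pid <- 0
    for (ci in seq_along(cfg$conditions)) {
      cond <- cfg$conditions[ci]
      c80 <- as.numeric(ci == 2)
      c50 <- as.numeric(ci == 3)
      for (p in seq_len(cfg$n_plates_per_condition)) {
        pid <- pid + 1
        u <- if (cfg$plate_sd > 0) stats::rnorm(1, 0, cfg$plate_sd) else 0
        n_w <- if (length(cfg$wells_per_plate) == 2)
          sample(cfg$wells_per_plate[1]:cfg$wells_per_plate[2], 1)
        else as.integer(cfg$wells_per_plate[1])
        eta <- cfg$beta[1] + cfg$beta[2] * tc + cfg$beta[3] * c80 +
          cfg$beta[4] * c50 + cfg$beta[5] * tc * c80 + cfg$beta[6] * tc * c50 + u
        k <- stats::rbinom(length(tc), n_w, stats::plogis(eta))
        rows[[pid]] <- data.frame(
          plate_id = sprintf("P%03d", pid), condition = cond, week = cfg$weeks,
          n_wells = n_w, n_oscillating = k, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "beta") <- cfg$beta
    out
  })
}
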