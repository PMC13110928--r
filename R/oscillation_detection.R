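#' Frequency band definition
#'
#' A band carries its edges plus the two detector constants that scale with
#' frequency: the minimum number of cycles an event must span and the gap
#' allowance (in cycles of the band center) across which sub-threshold dips
#' are bridged.
#'
#' @param name band label.
#' @param f_low,f_high band edges, Hz.
#' @param min_cycles minimum event length in cycles of the band center
#'   frequency.
#' @param gap_allowance_cycles sub-threshold gap (cycles of the band center)
#'   across which adjacent candidates are merged.
#' @return object of class `frequency_band`.
#' @export
frequency_band <- function(name, f_low, f_high, min_cycles,
                           gap_allowance_cycles) {
  if (!(f_low > 0 && f_low < f_high)) stop("need 0 < f_low < f_high")
  structure(list(name = name, f_low = f_low, f_high = f_high,
                 min_cycles = min_cycles,
                 gap_allowance_cycles = gap_allowance_cycles,
                 f_center = (f_low + f_high) / 2,
                 bandwidth = f_high - f_low),
            class = "frequency_band")
}

#' Canonical nested-oscillation bands
#'
#' Delta 1-4 Hz (8 cycles minimum, 3-cycle gap allowance), theta 4-8 Hz
#' (16, 4) and alpha 8-13 Hz (24, 5).
#'
#' @return named list of [frequency_band()] objects.
#' @export
default_bands <- function() {
  list(delta = frequency_band("delta", 1, 4, 8, 3),
       theta = frequency_band("theta", 4, 8, 16, 4),
       alpha = frequency_band("alpha", 8, 13, 24, 5))
}

#' Detection parameters for the dual-threshold method
#'
#' @param low_percentile,high_percentile percentile thresholds (of the
#'   smoothed amplitude envelope over the full recording) that a candidate
#'   must exceed continuously (low) and at least once (high).
#' @param c1,c2 constants of the envelope-smoothing width
#'   `sigma_seconds = c1 / f_center + c2 / bandwidth`.
#' @param min_spectral_duration minimum event duration (s) for spectral
#'   analysis.
#' @return object of class `detection_params`.
#' @export
detection_params <- function(low_percentile = 50, high_percentile = 75,
                             c1 = 0.25, c2 = 0.25,
                             min_spectral_duration = 1.0) {
  if (!(low_percentile >= 0 && low_percentile < high_percentile &&
        high_percentile <= 100))
    stop("need 0 <= low_percentile < high_percentile <= 100")
  structure(list(low_percentile = low_percentile,
                 high_percentile = high_percentile, c1 = c1, c2 = c2,
                 min_spectral_duration = min_spectral_duration),
            class = "detection_params")
}

#' Zero-phase FIR bandpass filter
#'
#' Hamming windowed-sinc FIR (order: three cycles of `f_low`, rounded to an
#' odd tap count) applied by linear convolution with the group delay removed,
#' so the output is zero-phase and sample-aligned with the input.
#'
#' @param x numeric series or `population_signal`.
#' @param band a [frequency_band()].
#' @param fs sampling rate, Hz (taken from the signal if omitted).
#' @return filtered numeric series, same length as the input.
#' @export
bandpass <- function(x, band, fs = NULL) {
  if (inherits(x, "population_signal")) {
    fs <- x$fs
    x <- x$values
  }
  if (is.null(fs)) stop("fs must be supplied for a bare numeric series")
  if (band$f_high >= fs / 2) stop("band extends to or beyond Nyquist")
  ntaps <- round(3 * fs / band$f_low)
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1  # type-I linear phase
  if (ntaps >= length(x))
    stop("signal too short for the filter order (", ntaps, " taps)")
  h <- signal::fir1(ntaps - 1, c(band$f_low, band$f_high) / (fs / 2),
                    type = "pass")
  gd <- (ntaps - 1) / 2
  full <- stats::convolve(x, rev(h), type = "open")
  full[(gd + 1):(gd + length(x))]
}

#' Amplitude envelope via the analytic signal
#'
#' Magnitude of the FFT-constructed analytic signal (Hilbert transform in
#' quadrature); for a pure sinusoid of amplitude A the envelope is A away
#' from the edges.
#'
#' @param x band-filtered numeric series.
#' @return non-negative envelope series, same length.
#' @export
amplitude_envelope <- function(x) {
  n <- length(x)
  if (n == 0) return(numeric(0))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# sigma (seconds) of the band-adaptive Gaussian envelope smoother
smoothing_sigma <- function(band, params) {
  params$c1 / band$f_center + params$c2 / band$bandwidth
}

#' Gaussian-smooth an amplitude envelope
#'
#' Convolution with a normalized Gaussian kernel whose width scales with the
#' band: `sigma = c1 / f_center + c2 / bandwidth` seconds (0.104 s for theta
#' at the defaults). Reflect padding preserves the series mean.
#'
#' @param env envelope series.
#' @param band a [frequency_band()].
#' @param fs sampling rate, Hz.
#' @param params a [detection_params()].
#' @return smoothed envelope, same length.
#' @export
smooth_envelope <- function(env, band, fs, params = detection_params()) {
  sigma <- smoothing_sigma(band, params) * fs
  if (sigma <= 0) stop("smoothing sigma must be positive")
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  n <- length(env)
  pad <- min(half, n - 1)
  padded <- c(rev(env[seq_len(pad) + 1]), env,
              rev(env[(n - pad):(n - 1)]))
  full <- stats::convolve(padded, rev(k), type = "open")
  full[(half + pad + 1):(half + pad + n)]
}

#' Detect oscillation events by dual-percentile thresholding
#'
#' Candidates are maximal runs of samples strictly above the low-percentile
#' threshold of the full-recording smoothed envelope. Adjacent candidates
#' separated by a sub-threshold gap of at most `gap_allowance_cycles /
#' f_center` seconds are merged; merged candidates are kept when (i) their
#' maximum strictly exceeds the high-percentile threshold and (ii) they span
#' at least `min_cycles` cycles of the band center frequency.
#'
#' @param smoothed smoothed envelope from [smooth_envelope()].
#' @param band a [frequency_band()].
#' @param fs sampling rate, Hz.
#' @param params a [detection_params()].
#' @param well_id well identifier carried into the output.
#' @return data.frame of events: `well_id, band, start_s, end_s, duration_s,
#'   n_cycles, peak_envelope`, in time order, non-overlapping. Zero rows when
#'   nothing is detected.
#' @export
detect_events <- function(smoothed, band, fs, params = detection_params(),
                          well_id = "well") {
  thr <- stats::quantile(smoothed,
                         c(params$low_percentile, params$high_percentile) / 100,
                         names = FALSE, type = 7)
  lo <- thr[1]
  hi <- thr[2]
  above <- smoothed > lo
  runs <- run_bounds(above)
  empty <- data.frame(well_id = character(0), band = character(0),
                      start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0), n_cycles = numeric(0),
                      peak_envelope = numeric(0), stringsAsFactors = FALSE)
  if (nrow(runs) == 0) return(empty)
  gap_s <- band$gap_allowance_cycles / band$f_center
  runs <- merge_runs(runs, max_gap = gap_s * fs)
  keep <- logical(nrow(runs))
  peak <- numeric(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    peak[i] <- max(smoothed[runs$first[i]:runs$last[i]])
    dur <- (runs$last[i] - runs$first[i] + 1) / fs
    keep[i] <- peak[i] > hi && dur * band$f_center >= band$min_cycles
  }
  runs <- runs[keep, , drop = FALSE]
  peak <- peak[keep]
  if (nrow(runs) == 0) return(empty)
  dur <- (runs$last - runs$first + 1) / fs
  data.frame(well_id = well_id, band = band$name,
             start_s = (runs$first - 1) / fs, end_s = runs$last / fs,
             duration_s = dur, n_cycles = dur * band$f_center,
             peak_envelope = peak, stringsAsFactors = FALSE)
}

# maximal TRUE runs of a logical vector -> data.frame(first, last)
run_bounds <- function(above) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(first = starts[r$values], last = ends[r$values])
}

# merge runs whose inter-run gap (samples) is <= max_gap
merge_runs <- function(runs, max_gap) {
  if (nrow(runs) <= 1) return(runs)
  first <- runs$first
  last <- runs$last
  out_f <- first[1]
  out_l <- last[1]
  for (i in 2:nrow(runs)) {
    if (first[i] - out_l[length(out_l)] - 1 <= max_gap) {
      out_l[length(out_l)] <- last[i]
    } else {
      out_f <- c(out_f, first[i])
      out_l <- c(out_l, last[i])
    }
  }
  data.frame(first = out_f, last = out_l)
}

#' Detect nested-oscillation events in every band
#'
#' Runs bandpass, Hilbert envelope, Gaussian smoothing and dual-threshold
#' detection independently per band on a population signal.
#'
#' @param signal a `population_signal`.
#' @param bands list of [frequency_band()]s (default [default_bands()]).
#' @param params a [detection_params()].
#' @return data.frame of events across bands (columns as [detect_events()]),
#'   ordered by band then time.
#' @export
detect_all_bands <- function(signal, bands = default_bands(),
                             params = detection_params()) {
  stopifnot(inherits(signal, "population_signal"))
  out <- lapply(bands, function(b) {
    filt <- bandpass(signal, b)
    env <- amplitude_envelope(filt)
    sm <- smooth_envelope(env, b, signal$fs, params)
    detect_events(sm, b, signal$fs, params, well_id = signal$well_id)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
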