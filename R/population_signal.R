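#' Double-exponential kernel parameters
#'
#' The kernel `k(t) = exp(-t / tau_decay) - exp(-t / tau_rise)` mimics the
#' time course of a glutamatergic postsynaptic response; convolving the
#' well-wide spike histogram with it yields a continuous population signal,
#' analogous to LFP proxies built from spikes in network models. Defaults:
#' 2 ms rise, 25 ms decay, 300 ms support.
#'
#' @param tau_rise rise time constant, seconds.
#' @param tau_decay decay time constant, seconds; must exceed `tau_rise`.
#' @param window kernel support, seconds; must be at least `5 * tau_decay` so
#'   the truncated tail is negligible.
#' @return object of class `kernel_params`.
#' @export
kernel_params <- function(tau_rise = 0.002, tau_decay = 0.025, window = 0.300) {
  if (!(tau_rise > 0 && tau_rise < tau_decay))
    stop("need 0 < tau_rise < tau_decay")
  if (window < 5 * tau_decay)
    stop("window must be >= 5 * tau_decay")
  structure(list(tau_rise = tau_rise, tau_decay = tau_decay, window = window),
            class = "kernel_params")
}

#' Bin a well's spikes into a population histogram
#'
#' Counts spikes from all electrodes into half-open bins
#' `[b*w, (b+1)*w)`; with the default 2 ms bins this yields a 500 Hz count
#' series.
#'
#' @param recording a [well_recording()].
#' @param bin_width bin width in seconds (default 0.002).
#' @return integer vector of length `ceiling(duration / bin_width)`.
#' @export
bin_spikes <- function(recording, bin_width = 0.002) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  n_bins <- as.integer(ceiling(recording$duration / bin_width - 1e-9))
  t <- unlist(recording$electrode_spikes, use.names = FALSE)
  if (length(t) == 0) return(integer(n_bins))
  idx <- floor(t / bin_width) + 1L
  idx[idx > n_bins] <- n_bins  # guards t == duration after rounding
  tabulate(idx, nbins = n_bins)
}

#' Evaluate the double-exponential kernel
#'
#' Samples `k(t) = exp(-t/tau_decay) - exp(-t/tau_rise)` at
#' `t = 0, 1/fs, ..., window` and rescales to unit peak. `k(0) = 0` and the
#' analytic peak time is `tau_r*tau_d/(tau_d - tau_r) * log(tau_d/tau_r)`
#' (about 5.49 ms at the defaults).
#'
#' @param params a [kernel_params()].
#' @param fs sampling rate, Hz (default 500).
#' @return numeric kernel vector with unit maximum.
#' @export
make_kernel <- function(params = kernel_params(), fs = 500) {
  stopifnot(inherits(params, "kernel_params"))
  t <- seq(0, params$window, by = 1 / fs)
  k <- exp(-t / params$tau_decay) - exp(-t / params$tau_rise)
  k / max(k)
}

#' Analytic peak time of the double-exponential kernel
#' @inheritParams make_kernel
#' @return peak time `t*` in seconds.
#' @export
kernel_peak_time <- function(params = kernel_params()) {
  with(params, tau_rise * tau_decay / (tau_decay - tau_rise) *
         log(tau_decay / tau_rise))
}

#' Convolve a spike histogram into a continuous population signal
#'
#' Causal linear convolution truncated to the input length, so sample `n`
#' maps to time `(n - 1) / fs` throughout the pipeline and a single spike
#' reproduces the kernel shape exactly.
#'
#' @param histogram spike-count vector from [bin_spikes()].
#' @param kernel kernel vector from [make_kernel()].
#' @param fs sampling rate, Hz.
#' @param well_id carried through for bookkeeping.
#' @return object of class `population_signal`: list with `values`, `fs`,
#'   `bin_width`, `t0`, `well_id`.
#' @export
convolve_signal <- function(histogram, kernel, fs = 500, well_id = "well") {
  if (length(histogram) == 0 || length(kernel) == 0)
    stop("histogram and kernel must be non-empty")
  if (length(kernel) > length(histogram))
    stop("kernel must be shorter than the histogram")
  full <- stats::convolve(as.numeric(histogram), rev(as.numeric(kernel)),
                          type = "open")
  vals <- full[seq_along(histogram)]
  vals[vals < 0 & vals > -1e-9] <- 0  # FFT round-off
  structure(list(values = vals, fs = fs, bin_width = 1 / fs, t0 = 0,
                 well_id = well_id),
            class = "population_signal")
}

#' Spike train to population signal, in one step
#'
#' Bins all electrodes' spikes at `1/fs` resolution and convolves with the
#' double-exponential kernel: the standard front end for all oscillation and
#' spectral analysis.
#'
#' @param recording a [well_recording()].
#' @param params a [kernel_params()].
#' @param fs sampling rate, Hz (default 500, i.e. 2 ms bins).
#' @return a `population_signal`.
#' @export
population_signal <- function(recording, params = kernel_params(), fs = 500) {
  h <- bin_spikes(recording, bin_width = 1 / fs)
  convolve_signal(h, make_kernel(params, fs), fs = fs,
                  well_id = recording$well_id)
}

#' @export
print.population_signal <- function(x, ...) {
  cat(sprintf("<population_signal> %s: %d samples @ %g Hz (%.1f s)\n",
              x$well_id, length(x$values), x$fs, length(x$values) / x$fs))
  invisible(x)
}

#' Time axis of a population signal
#' @param signal a `population_signal`.
#' @return numeric vector of sample times (seconds).
#' @export
signal_times <- function(signal) {
  signal$t0 + (seq_along(signal$values) - 1) / signal$fs
}
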