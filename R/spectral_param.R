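#' Welch spectral-estimation parameters
#'
#' @param segment_length segment length, seconds (default 4).
#' @param overlap segment overlap, seconds (default 2).
#' @param f_min,f_max analyzed frequency range, Hz (defaults 0.05-40).
#' @param taper window; only `"hann"` is implemented.
#' @return object of class `welch_params`.
#' @export
welch_params <- function(segment_length = 4, overlap = 2, f_min = 0.05,
                         f_max = 40, taper = "hann") {
  if (!(overlap >= 0 && overlap < segment_length))
    stop("need 0 <= overlap < segment_length")
  if (!(f_min < f_max)) stop("need f_min < f_max")
  if (!identical(taper, "hann")) stop("only the Hann taper is implemented")
  structure(list(segment_length = segment_length, overlap = overlap,
                 f_min = f_min, f_max = f_max, taper = taper),
            class = "welch_params")
}

#' Welch power spectral density
#'
#' Averaged Hann-tapered periodogram (one-sided, density scaling, constant
#' detrend per segment). Segments shorter than `segment_length` arise for
#' brief oscillation events: the effective segment is then
#' `min(segment_length, signal duration)` with 50% overlap, so a 1-4 s event
#' is analyzed as a single (or two half-overlapping) tapered segment(s).
#'
#' @param x numeric series or `population_signal` (a signal segment).
#' @param fs sampling rate, Hz (taken from the signal if omitted).
#' @param params a [welch_params()].
#' @return list with `freqs` (Hz, restricted to `[f_min, f_max]`) and `psd`
#'   (power/Hz).
#' @export
welch_psd <- function(x, fs = NULL, params = welch_params()) {
  if (inherits(x, "population_signal")) {
    fs <- x$fs
    x <- x$values
  }
  if (is.null(fs)) stop("fs must be supplied for a bare numeric series")
  n <- length(x)
  dur <- n / fs
  seg_s <- min(params$segment_length, dur)
  nper <- max(8L, round(seg_s * fs))
  if (nper > n) nper <- n
  over_s <- if (seg_s < params$segment_length) seg_s / 2 else params$overlap
  nover <- round(over_s / seg_s * nper)
  step <- max(1L, nper - nover)
  starts <- seq(1L, n - nper + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nper - 1) / (nper - 1)))
  u <- sum(w^2)
  nfreq <- nper %/% 2 + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)[seq_len(nfreq)]
    acc <- acc + Mod(X)^2
  }
  p <- acc / (length(starts) * fs * u)
  # one-sided: double everything except DC (and Nyquist when nper is even)
  dbl <- rep(2, nfreq)
  dbl[1] <- 1
  if (nper %% 2 == 0) dbl[nfreq] <- 1
  p <- p * dbl
  f <- (seq_len(nfreq) - 1) * fs / nper
  keep <- f >= params$f_min & f <= params$f_max
  list(freqs = f[keep], psd = p[keep])
}

#' Spectral-parameterization settings
#'
#' Settings of the aperiodic + Gaussian-peak decomposition: peak width limits
#' 1-8 Hz, minimum peak height 0.2 (log10 power above the aperiodic fit),
#' at most 4 peaks, relative peak threshold 1.5 SD of the flattened spectrum,
#' fixed (no-knee) aperiodic mode.
#'
#' @param peak_width_limits length-2 Hz limits on peak bandwidth
#'   (bandwidth = 2 * Gaussian sd).
#' @param min_peak_height absolute height threshold, log10-power units.
#' @param max_n_peaks maximum number of peaks.
#' @param peak_threshold relative height threshold, in SD of the flattened
#'   spectrum.
#' @param aperiodic_mode only `"fixed"` is implemented.
#' @return object of class `specfit_settings`.
#' @export
specfit_settings <- function(peak_width_limits = c(1, 8),
                             min_peak_height = 0.2, max_n_peaks = 4,
                             peak_threshold = 1.5,
                             aperiodic_mode = "fixed") {
  if (length(peak_width_limits) != 2 || peak_width_limits[1] <= 0 ||
      peak_width_limits[1] >= peak_width_limits[2])
    stop("peak_width_limits must be an increasing positive pair")
  if (max_n_peaks < 0) stop("max_n_peaks must be >= 0")
  if (!identical(aperiodic_mode, "fixed"))
    stop("only the fixed (no-knee) aperiodic mode is implemented")
  structure(list(peak_width_limits = peak_width_limits,
                 min_peak_height = min_peak_height,
                 max_n_peaks = as.integer(max_n_peaks),
                 peak_threshold = peak_threshold,
                 aperiodic_mode = aperiodic_mode),
            class = "specfit_settings")
}

# ordinary least-squares aperiodic fit in log-log space:
# log10 psd = offset - exponent * log10 f
ap_fit_ols <- function(logf, logp) {
  cf <- stats::lm.fit(cbind(1, logf), logp)$coefficients
  c(offset = unname(cf[1]), exponent = unname(-cf[2]))
}

ap_model <- function(logf, ap) ap[["offset"]] - ap[["exponent"]] * logf

# robust aperiodic fit: OLS, then refit on the half of points with the
# smallest signed residuals (peaks only push residuals up, so the lower half
# is peak-free)
ap_fit_robust <- function(logf, logp) {
  ap <- ap_fit_ols(logf, logp)
  res <- logp - ap_model(logf, ap)
  keep <- res <= stats::median(res)
  ap_fit_ols(logf[keep], logp[keep])
}

gaussian_profile <- function(f, center, height, sd) {
  height * exp(-(f - center)^2 / (2 * sd^2))
}

peaks_model <- function(f, peaks) {
  out <- numeric(length(f))
  if (is.null(peaks) || nrow(peaks) == 0) return(out)
  for (i in seq_len(nrow(peaks)))
    out <- out + gaussian_profile(f, peaks$center[i], peaks$height[i],
                                  peaks$bandwidth[i] / 2)
  out
}

# iterative peak guessing on a flattened spectrum
guess_peaks <- function(f, flat, settings) {
  sd_lims <- settings$peak_width_limits / 2
  guesses <- list()
  work <- flat
  for (k in seq_len(settings$max_n_peaks)) {
    i <- which.max(work)
    h <- work[i]
    if (h <= settings$peak_threshold * stats::sd(work)) break
    if (h <= settings$min_peak_height) break
    # half-height width estimate from the nearer flank
    half <- h / 2
    ri <- i
    while (ri < length(work) && work[ri] > half) ri <- ri + 1
    li <- i
    while (li > 1 && work[li] > half) li <- li - 1
    dr <- if (work[ri] <= half) f[ri] - f[i] else NA
    dl <- if (work[li] <= half) f[i] - f[li] else NA
    hwhm <- min(dr, dl, na.rm = TRUE)
    sdg <- if (is.finite(hwhm) && hwhm > 0) hwhm / sqrt(2 * log(2))
           else mean(sd_lims)
    sdg <- min(max(sdg, sd_lims[1]), sd_lims[2])
    guesses[[k]] <- c(center = f[i], height = h, sd = sdg)
    work <- work - gaussian_profile(f, f[i], h, sdg)
  }
  guesses
}

# joint least-squares refit of all Gaussians on the flattened spectrum
refit_peaks <- function(f, flat, guesses, settings) {
  if (length(guesses) == 0)
    return(data.frame(center = numeric(0), height = numeric(0),
                      bandwidth = numeric(0)))
  sd_lims <- settings$peak_width_limits / 2
  p0 <- unlist(guesses)
  lower <- upper <- numeric(length(p0))
  for (k in seq_along(guesses)) {
    j <- 3 * (k - 1)
    g <- guesses[[k]]
    lower[j + 1] <- max(min(f), g[["center"]] - 2 * g[["sd"]])
    upper[j + 1] <- min(max(f), g[["center"]] + 2 * g[["sd"]])
    lower[j + 2] <- 0
    upper[j + 2] <- Inf
    lower[j + 3] <- sd_lims[1]
    upper[j + 3] <- sd_lims[2]
  }
  obj <- function(p) {
    m <- numeric(length(f))
    for (k in seq_along(guesses)) {
      j <- 3 * (k - 1)
      m <- m + gaussian_profile(f, p[j + 1], p[j + 2], p[j + 3])
    }
    sum((flat - m)^2)
  }
  fit <- stats::optim(p0, obj, method = "L-BFGS-B", lower = lower,
                      upper = upper, control = list(maxit = 500))
  p <- fit$par
  idx <- seq_along(guesses)
  out <- data.frame(center = p[3 * (idx - 1) + 1],
                    height = p[3 * (idx - 1) + 2],
                    bandwidth = 2 * p[3 * (idx - 1) + 3])
  out <- out[out$height > 0, , drop = FALSE]
  out[order(out$center), , drop = FALSE]
}

#' Parameterize a power spectrum into aperiodic and periodic components
#'
#' Decomposes `log10 psd(f)` into an aperiodic power law
#' `offset - exponent * log10 f` and up to `max_n_peaks` Gaussian peaks:
#' (1) robust aperiodic fit (OLS, refit on the lowest-residual half);
#' (2) iterative peak extraction on the flattened spectrum — the running
#' maximum is accepted while it exceeds both the absolute
#' (`min_peak_height`) and relative (`peak_threshold` SD) thresholds, its
#' width guessed from the half-height flank; (3) joint multi-Gaussian
#' least-squares refit; (4) final aperiodic refit on the peak-removed
#' spectrum.
#'
#' @param freqs frequency axis, Hz (positive, >= 8 points).
#' @param psd linear power values (positive).
#' @param settings a [specfit_settings()].
#' @return object of class `spectral_fit`: `freqs`, `log_psd`, `offset`,
#'   `exponent`, `peaks` (data.frame center/height/bandwidth), `flattened`,
#'   `model` (fitted log10 spectrum), `r_squared`, `error` (MAE).
#' @export
fit_spectrum <- function(freqs, psd, settings = specfit_settings()) {
  if (length(freqs) != length(psd)) stop("freqs and psd lengths differ")
  keep <- freqs > 0
  freqs <- freqs[keep]
  psd <- psd[keep]
  if (length(freqs) < 8) stop("need at least 8 positive-frequency points")
  if (any(!is.finite(psd)) || any(psd <= 0))
    stop("psd must be finite and strictly positive (log-power fit)")
  logf <- log10(freqs)
  logp <- log10(psd)
  ap <- ap_fit_robust(logf, logp)
  flat <- logp - ap_model(logf, ap)
  guesses <- guess_peaks(freqs, flat, settings)
  peaks <- refit_peaks(freqs, flat, guesses, settings)
  # final aperiodic refit with the fitted peaks removed
  ap <- ap_fit_ols(logf, logp - peaks_model(freqs, peaks))
  flat <- logp - ap_model(logf, ap)
  model <- ap_model(logf, ap) + peaks_model(freqs, peaks)
  resid <- logp - model
  r2 <- 1 - sum(resid^2) / sum((logp - mean(logp))^2)
  structure(list(freqs = freqs, log_psd = logp,
                 offset = ap[["offset"]], exponent = ap[["exponent"]],
                 peaks = peaks, flattened = flat, model = model,
                 r_squared = r2, error = mean(abs(resid))),
            class = "spectral_fit")
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat(sprintf("<spectral_fit> offset %.3f, exponent %.3f, %d peak(s), R2 %.3f\n",
              x$offset, x$exponent, nrow(x$peaks), x$r_squared))
  if (nrow(x$peaks) > 0) print(round(x$peaks, 3))
  invisible(x)
}

#' In-band maximum of the flattened spectrum
#'
#' Peak frequency and aperiodic-corrected power of a band: the argmax of the
#' flattened (aperiodic-subtracted) spectrum restricted to the band edges.
#' Ties resolve to the lowest frequency. Returns `NULL` when the flattened
#' maximum is not positive (no in-band power above the aperiodic fit).
#'
#' @param fit a [fit_spectrum()] result.
#' @param band a [frequency_band()].
#' @return list with `band`, `peak_freq`, `peak_power`, or `NULL`.
#' @export
band_peak <- function(fit, band) {
  stopifnot(inherits(fit, "spectral_fit"))
  sel <- fit$freqs >= band$f_low & fit$freqs <= band$f_high
  if (!any(sel)) stop("fitted spectrum does not cover band ", band$name)
  flat <- fit$flattened[sel]
  i <- which.max(flat)
  if (flat[i] <= 0) return(NULL)
  list(band = band$name, peak_freq = fit$freqs[sel][i], peak_power = flat[i])
}

#' Annotate oscillation events with spectral fits
#'
#' For each detected event lasting at least `min_duration` seconds, computes
#' the Welch spectrum of the corresponding signal stretch, parameterizes it,
#' and records the aperiodic offset/exponent plus the in-band peak of the
#' event's own band. Shorter events keep `NA` spectral fields.
#'
#' @param signal the `population_signal` the events were detected on.
#' @param events event data.frame from [detect_all_bands()].
#' @param welch a [welch_params()].
#' @param settings a [specfit_settings()].
#' @param bands band list matching the event table's `band` column.
#' @param min_duration minimum event duration for spectral analysis, seconds.
#' @return the event data.frame with columns `peak_freq_hz, peak_power,
#'   offset, exponent` added.
#' @export
event_spectra <- function(signal, events, welch = welch_params(),
                          settings = specfit_settings(),
                          bands = default_bands(), min_duration = 1.0) {
  stopifnot(inherits(signal, "population_signal"))
  events <- as.data.frame(events)
  n <- nrow(events)
  events$peak_freq_hz <- rep(NA_real_, n)
  events$peak_power <- rep(NA_real_, n)
  events$offset <- rep(NA_real_, n)
  events$exponent <- rep(NA_real_, n)
  if (n == 0) return(events)
  fs <- signal$fs
  for (i in seq_len(n)) {
    if (events$duration_s[i] < min_duration) next
    i0 <- max(1L, floor(events$start_s[i] * fs) + 1L)
    i1 <- min(length(signal$values), ceiling(events$end_s[i] * fs))
    seg <- signal$values[i0:i1]
    fit <- tryCatch({
      ps <- welch_psd(seg, fs, welch)
      pos <- ps$psd > 0
      fit_spectrum(ps$freqs[pos], ps$psd[pos], settings)
    }, error = function(e) NULL)
    if (is.null(fit)) next
    events$offset[i] <- fit$offset
    events$exponent[i] <- fit$exponent
    b <- bands[[events$band[i]]]
    if (!is.null(b)) {
      bp <- tryCatch(band_peak(fit, b), error = function(e) NULL)
      if (!is.null(bp)) {
        events$peak_freq_hz[i] <- bp$peak_freq
        events$peak_power[i] <- bp$peak_power
      }
    }
  }
  events
}
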