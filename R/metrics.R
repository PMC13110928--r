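#' Per-well, per-band oscillation metrics
#'
#' Summarizes detected nested-oscillation events per band: event count, mean
#' duration, occurrence rate (events/minute), means of the spectral
#' annotations over fitted events, and the percentage of network bursts that
#' overlap at least one event of the band ("% oscillatory bursts"). Any
#' positive time overlap counts; `pct_oscillatory_nbs` is `NA` when the well
#' has no network bursts, and spectral means are `NA` when no event carries a
#' fit.
#'
#' @param events event data.frame (from [detect_all_bands()] /
#'   [event_spectra()]) for one well.
#' @param network_bursts network-burst data.frame (`start`, `end`) for the
#'   same well.
#' @param recording the [well_recording()] the detections came from.
#' @param bands band list (default [default_bands()]); bands absent from the
#'   event table get zero-event rows.
#' @return data.frame, one row per band: `well_id, band, n_events,
#'   mean_duration, occurrence_rate, mean_peak_freq, mean_peak_power,
#'   mean_offset, mean_exponent, pct_oscillatory_nbs`.
#' @export
summarize_well <- function(events, network_bursts, recording,
                           bands = default_bands()) {
  events <- as.data.frame(events)
  minutes <- recording$duration / 60
  n_nb <- nrow(network_bursts)
  rows <- lapply(bands, function(b) {
    ev <- events[events$band == b$name, , drop = FALSE]
    n <- nrow(ev)
    mean_or_na <- function(x) {
      x <- x[is.finite(x)]
      if (length(x) == 0) NA_real_ else mean(x)
    }
    pct <- if (n_nb == 0) NA_real_ else {
      osc <- vapply(seq_len(n_nb), function(i) {
        any(ev$start_s < network_bursts$end[i] &
              ev$end_s > network_bursts$start[i])
      }, logical(1))
      100 * sum(osc) / n_nb
    }
    data.frame(
      well_id = recording$well_id, band = b$name, n_events = n,
      mean_duration = if (n > 0) mean(ev$duration_s) else NA_real_,
      occurrence_rate = n / minutes,
      mean_peak_freq = if (n > 0) mean_or_na(ev$peak_freq_hz) else NA_real_,
      mean_peak_power = if (n > 0) mean_or_na(ev$peak_power) else NA_real_,
      mean_offset = if (n > 0) mean_or_na(ev$offset) else NA_real_,
      mean_exponent = if (n > 0) mean_or_na(ev$exponent) else NA_real_,
      pct_oscillatory_nbs = pct, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Percent change from baseline
#'
#' `100 * (post - baseline) / baseline`, vectorized. Zero (or non-finite)
#' baselines yield `NA` with a warning.
#'
#' @param baseline,post numeric values on the same scale.
#' @return percent change (numeric).
#' @export
percent_change <- function(baseline, post) {
  bad <- !is.finite(baseline) | baseline == 0
  if (any(bad & is.finite(post)))
    warning("percent_change: zero or non-finite baseline yields NA")
  out <- 100 * (post - baseline) / baseline
  out[bad] <- NA_real_
  out
}

#' Burst- and network-burst-level spike metrics for one well
#'
#' Classical MEA activity summaries: weighted mean firing rate (total spikes
#' per second per active electrode), ISI coefficient of variation (SD/mean of
#' all within-electrode ISIs), burst %, NB % (percentages of spikes inside
#' bursts / network bursts), mean spikes per burst and per NB, and mean
#' burst / NB durations.
#'
#' @param recording a [well_recording()].
#' @param network_bursts network-burst data.frame (`start`, `end`).
#' @param bursts per-electrode burst data.frame (`start`, `end`, `n_spikes`),
#'   e.g. pooled output of [detect_bursts_isi()] across electrodes.
#' @param min_rate active-electrode criterion, spikes/minute.
#' @return one-row data.frame: `well_id, wmfr, isi_cov, n_bursts,
#'   spikes_per_burst, burst_duration, burst_pct, n_nbs, spikes_per_nb,
#'   nb_duration, nb_pct`.
#' @export
nb_spike_metrics <- function(recording, network_bursts, bursts,
                             min_rate = 5) {
  act <- active_electrodes(recording, min_rate)
  total <- n_spikes(recording)
  pool <- pooled_spikes(recording)
  isis <- unlist(lapply(recording$electrode_spikes,
                        function(x) if (length(x) > 1) diff(x) else numeric(0)),
                 use.names = FALSE)
  in_any <- function(times, tab) {
    if (nrow(tab) == 0 || length(times) == 0) return(rep(FALSE, length(times)))
    hit <- rep(FALSE, length(times))
    for (i in seq_len(nrow(tab)))
      hit <- hit | (times >= tab$start[i] & times <= tab$end[i])
    hit
  }
  in_b <- in_any(pool$time, bursts)
  in_nb <- in_any(pool$time, network_bursts)
  data.frame(
    well_id = recording$well_id,
    wmfr = if (length(act) > 0) total / (recording$duration * length(act))
           else NA_real_,
    isi_cov = if (length(isis) > 1 && mean(isis) > 0)
      stats::sd(isis) / mean(isis) else NA_real_,
    n_bursts = nrow(bursts),
    spikes_per_burst = if (nrow(bursts) > 0) mean(bursts$n_spikes) else NA_real_,
    burst_duration = if (nrow(bursts) > 0) mean(bursts$end - bursts$start)
                     else NA_real_,
    burst_pct = if (total > 0) 100 * sum(in_b) / total else NA_real_,
    n_nbs = nrow(network_bursts),
    spikes_per_nb = if (nrow(network_bursts) > 0)
      sum(in_nb) / nrow(network_bursts) else NA_real_,
    nb_duration = if (nrow(network_bursts) > 0)
      mean(network_bursts$end - network_bursts$start) else NA_real_,
    nb_pct = if (total > 0) 100 * sum(in_nb) / total else NA_real_,
    stringsAsFactors = FALSE)
}

#' Plate-level oscillating-well occurrence table
#'
#' A well counts as oscillating at a week when it has at least `min_events`
#' detected events (any band) that week. Only wells that are network-burst
#' eligible (listed in `eligible_wells`, e.g. wells with at least one NB at
#' the final week) enter numerator and denominator.
#'
#' @param well_table data.frame with one row per (well, week):
#'   `well_id, plate_id, condition, week, n_events`.
#' @param eligible_wells character vector of eligible well ids.
#' @param min_events events needed to call a well oscillating (default 1).
#' @return occurrence data.frame: `plate_id, condition, week, n_wells,
#'   n_oscillating`.
#' @export
oscillating_wells <- function(well_table, eligible_wells, min_events = 1) {
  wt <- as.data.frame(well_table)
  need <- c("well_id", "plate_id", "condition", "week", "n_events")
  missing_cols <- setdiff(need, names(wt))
  if (length(missing_cols) > 0)
    stop("well_table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  wt <- wt[wt$well_id %in% eligible_wells, , drop = FALSE]
  if (nrow(wt) == 0)
    return(data.frame(plate_id = character(0), condition = character(0),
                      week = numeric(0), n_wells = integer(0),
                      n_oscillating = integer(0)))
  key <- interaction(wt$plate_id, wt$week, drop = TRUE)
  rows <- lapply(split(wt, key), function(g) {
    data.frame(plate_id = g$plate_id[1], condition = g$condition[1],
               week = g$week[1], n_wells = nrow(g),
               n_oscillating = sum(g$n_events >= min_events),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$plate_id, res$week), , drop = FALSE]
  rownames(res) <- NULL
  res
}
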