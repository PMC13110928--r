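#' Construct a well recording
#'
#' A `well_recording` holds every spike time recorded from one MEA well over
#' one session: a named list of per-electrode spike-time vectors (seconds from
#' recording start), the recording duration, and free-form metadata (plate id,
#' condition label, weeks post-plating, ...).
#'
#' Times use a half-open convention `[0, duration)`; spikes are sorted within
#' each electrode.
#'
#' @param electrode_spikes named list; one sorted numeric vector of spike times
#'   (seconds) per electrode. Names are electrode ids (e.g. `"A1"`).
#' @param duration recording length in seconds. If `NULL`, the maximum spike
#'   time rounded up to a whole second is used.
#' @param well_id well identifier.
#' @param metadata named list of additional fields (condition, plate_id, week,
#'   treatment, ...).
#' @return An object of class `well_recording`.
#' @export
well_recording <- function(electrode_spikes, duration = NULL, well_id = "well",
                           metadata = list()) {
  if (!is.list(electrode_spikes) || length(electrode_spikes) < 1L)
    stop("`electrode_spikes` must be a non-empty named list of numeric vectors")
  if (is.null(names(electrode_spikes)) || anyNA(names(electrode_spikes)))
    stop("`electrode_spikes` must be named by electrode id")
  electrode_spikes <- lapply(electrode_spikes, function(x) {
    x <- as.numeric(x)
    if (anyNA(x) || any(!is.finite(x))) stop("spike times must be finite")
    if (any(x < 0)) stop("spike times must be non-negative")
    sort(x)
  })
  if (is.null(duration)) {
    mx <- suppressWarnings(max(unlist(electrode_spikes, use.names = FALSE), -Inf))
    duration <- if (is.finite(mx)) ceiling(mx) else 0
    if (duration == 0) duration <- 1
  }
  duration <- as.numeric(duration)
  if (!is.finite(duration) || duration <= 0) stop("`duration` must be positive")
  bad <- vapply(electrode_spikes, function(x) length(x) > 0 && max(x) >= duration,
                logical(1))
  if (any(bad)) stop("spike times must lie in [0, duration)")
  structure(
    list(well_id = as.character(well_id), electrode_spikes = electrode_spikes,
         duration = duration, metadata = metadata),
    class = "well_recording"
  )
}

#' @export
print.well_recording <- function(x, ...) {
  n <- sum(vapply(x$electrode_spikes, length, integer(1)))
  cat(sprintf("<well_recording> %s: %d electrodes, %d spikes, %.1f s\n",
              x$well_id, length(x$electrode_spikes), n, x$duration))
  invisible(x)
}

#' Total spike count of a recording
#' @param recording a [well_recording()].
#' @return integer spike count over all electrodes.
#' @export
n_spikes <- function(recording) {
  sum(vapply(recording$electrode_spikes, length, integer(1)))
}

#' Pool all electrodes into one sorted spike train
#'
#' Ties in time are broken by electrode id (alphabetical), so the pooled
#' ordering is deterministic.
#'
#' @param recording a [well_recording()].
#' @param electrodes optional character vector restricting which electrodes
#'   are pooled (default: all).
#' @return data.frame with columns `time`, `electrode`, sorted by time then
#'   electrode id.
#' @export
pooled_spikes <- function(recording, electrodes = NULL) {
  es <- recording$electrode_spikes
  if (!is.null(electrodes)) es <- es[intersect(names(es), electrodes)]
  if (length(es) == 0L)
    return(data.frame(time = numeric(0), electrode = character(0),
                      stringsAsFactors = FALSE))
  df <- data.frame(
    time = unlist(es, use.names = FALSE),
    electrode = rep(names(es), vapply(es, length, integer(1))),
    stringsAsFactors = FALSE
  )
  df[order(df$time, df$electrode), , drop = FALSE]
}

#' Read a spike-list CSV into well recordings
#'
#' The spike-list dialect is a plain UTF-8 CSV with header columns `well`,
#' `electrode`, `time_s` ('.' decimal separator) — the least-common-denominator
#' of plate-reader spike exports. An optional `duration_s` column (constant per
#' well) states the recording length; otherwise the duration is the maximum
#' spike time rounded up to a whole second.
#'
#' @param path CSV file path.
#' @param well_filter optional character vector of well ids to keep.
#' @param duration optional recording duration (seconds) applied to all wells,
#'   overriding any `duration_s` column.
#' @return list of [well_recording()] objects, one per well, named by well id.
#' @export
read_spike_list <- function(path, well_filter = NULL, duration = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "electrode", "time_s")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("spike list ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0) return(structure(list(), names = character(0)))
  t <- suppressWarnings(as.numeric(df$time_s))
  bad <- which(is.na(t) | !is.finite(t) | t < 0)
  if (length(bad) > 0)
    stop("unparseable or negative spike time at data line ", bad[1],
         " of ", path)
  df$time_s <- t
  if (!is.null(well_filter)) df <- df[df$well %in% well_filter, , drop = FALSE]
  out <- lapply(split(df, df$well), function(w) {
    dur <- duration
    if (is.null(dur) && "duration_s" %in% names(w)) dur <- w$duration_s[1]
    spikes <- lapply(split(w$time_s, w$electrode), sort)
    well_recording(spikes, duration = dur, well_id = w$well[1])
  })
  out[order(names(out))]
}

#' Write well recordings as a spike-list CSV
#'
#' Inverse of [read_spike_list()]: writes columns `well`, `electrode`,
#' `time_s`, `duration_s` in deterministic (well, electrode, time) order.
#'
#' @param recordings a [well_recording()] or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spike_list <- function(recordings, path) {
  if (inherits(recordings, "well_recording")) recordings <- list(recordings)
  rows <- lapply(recordings, function(rec) {
    df <- pooled_spikes(rec)
    # pooled order is (time, electrode); re-sort per electrode for readability
    df <- df[order(df$electrode, df$time), , drop = FALSE]
    if (nrow(df) == 0)
      return(data.frame(well = character(0), electrode = character(0),
                        time_s = numeric(0), duration_s = numeric(0)))
    data.frame(well = rec$well_id, electrode = df$electrode, time_s = df$time,
               duration_s = rec$duration, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(well = character(0), electrode = character(0),
                      time_s = numeric(0), duration_s = numeric(0))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an oscillation-event table
#'
#' Stable column order: `well_id, band, start_s, end_s, duration_s, n_cycles,
#' peak_envelope, peak_freq_hz, peak_power, offset, exponent`. Spectral columns
#' are `NA` for events without a spectral fit. Zero events yield a header-only
#' file.
#'
#' @param events event data.frame from [detect_all_bands()] /
#'   [event_spectra()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  cols <- c("well_id", "band", "start_s", "end_s", "duration_s", "n_cycles",
            "peak_envelope", "peak_freq_hz", "peak_power", "offset", "exponent")
  events <- as.data.frame(events)
  for (cl in setdiff(cols, names(events))) events[[cl]] <- rep(NA_real_, nrow(events))
  utils::write.csv(events[, cols, drop = FALSE], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read back an oscillation-event table
#' @param path CSV written by [write_events()].
#' @return event data.frame.
#' @export
read_events <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a metrics (or any result) table
#'
#' Lossless CSV serialization with columns in their current order.
#'
#' @param table data.frame of per-well metrics.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a plate-level occurrence table
#'
#' Columns `plate_id, condition, week, n_wells, n_oscillating`; one row per
#' plate and timepoint.
#'
#' @param table occurrence data.frame (see [simulate_occurrence()]).
#' @param path CSV path.
#' @return `path` (write) or the table (read).
#' @export
write_occurrence <- function(table, path) {
  cols <- c("plate_id", "condition", "week", "n_wells", "n_oscillating")
  table <- as.data.frame(table)[, cols, drop = FALSE]
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_occurrence
#' @export
read_occurrence <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate_id", "condition", "week", "n_wells", "n_oscillating")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("occurrence table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(df$n_oscillating > df$n_wells) || any(df$n_oscillating < 0))
    stop("n_oscillating must lie in [0, n_wells]")
  df
}
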