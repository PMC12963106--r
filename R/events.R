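#' Detect hypotension events on a 1 Hz MAP series
#'
#' A hypotension event is a maximal run of consecutive valid seconds with
#' MAP below `threshold` lasting at least `min_duration_s` (the standard
#' definition: MAP < 65 mmHg sustained for at least one minute). Invalid
#' (masked) seconds break runs, so an event is never asserted across missing
#' data; there is no gap merging by default.
#'
#' @param map_series a `map_series` from [beats_to_map_series()].
#' @param threshold_mmHg event threshold, mmHg.
#' @param min_duration_s minimum sustained duration, seconds.
#' @param merge_gap_s optional gap (seconds) across which adjacent
#'   sub-threshold runs are merged before the duration test; 0 (default)
#'   disables merging.
#' @return data.frame with one row per event: `onset_s`, `offset_s`,
#'   `duration_s`, `nadir_mmHg`, `aut_contribution` (mmHg*min below the
#'   threshold inside the event).
#' @export
detect_events <- function(map_series, threshold_mmHg = 65, min_duration_s = 60,
                          merge_gap_s = 0) {
  stopifnot(inherits(map_series, "map_series"))
  v <- map_series$values
  ok <- map_series$valid_mask & !is.na(v)
  below <- ok & v < threshold_mmHg
  r <- rle(as.vector(below))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (merge_gap_s > 0 && nrow(runs) > 1) {
    merged <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      j <- nrow(merged)
      gap <- runs$start[i] - merged$end[j] - 1
      if (gap <= merge_gap_s) merged$end[j] <- runs$end[i]
      else merged <- rbind(merged, runs[i, , drop = FALSE])
    }
    runs <- merged
  }
  runs <- runs[runs$end - runs$start + 1 >= min_duration_s, , drop = FALSE]
  t0 <- map_series$start_time_s
  out <- lapply(seq_len(nrow(runs)), function(i) {
    idx <- runs$start[i]:runs$end[i]
    data.frame(onset_s = t0 + runs$start[i] - 1,
               offset_s = t0 + runs$end[i],
               duration_s = runs$end[i] - runs$start[i] + 1,
               nadir_mmHg = min(v[idx], na.rm = TRUE),
               aut_contribution = sum(pmax(0, threshold_mmHg - v[idx]),
                                      na.rm = TRUE) / 60)
  })
  if (length(out) == 0) {
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      duration_s = numeric(0), nadir_mmHg = numeric(0),
                      aut_contribution = numeric(0)))
  }
  do.call(rbind, out)
}

#' Hypotension burden summary for one patient
#'
#' Computes the per-patient severity metrics: event count, total and mean
#' event duration, the fraction of valid time spent below the threshold, the
#' area under the threshold (AUT, mmHg*min, accumulated over ALL
#' sub-threshold seconds including sub-minute transients), the time-weighted
#' average (TWA = AUT / valid duration in minutes), and the mean MAP over
#' valid seconds.
#'
#' @param map_series a `map_series`.
#' @param events events from [detect_events()] on the same series.
#' @param threshold_mmHg burden threshold, mmHg.
#' @return one-row data.frame with `n_events`, `total_hypotension_min`,
#'   `mean_event_duration_min`, `time_fraction_below65` (percent),
#'   `aut_mmHg_min`, `twa_mmHg`, `mean_map_mmHg`.
#' @export
severity_summary <- function(map_series, events, threshold_mmHg = 65) {
  v <- map_series$values
  ok <- map_series$valid_mask & !is.na(v)
  n_valid <- sum(ok)
  if (n_valid == 0) stop("empty series: no valid seconds")
  below <- ok & v < threshold_mmHg
  aut <- sum(pmax(0, threshold_mmHg - v[below])) / 60
  data.frame(
    n_events = nrow(events),
    total_hypotension_min = sum(events$duration_s) / 60,
    mean_event_duration_min = if (nrow(events) == 0) 0 else mean(events$duration_s) / 60,
    time_fraction_below65 = 100 * sum(below) / n_valid,
    aut_mmHg_min = aut,
    twa_mmHg = aut / (n_valid / 60),
    mean_map_mmHg = mean(v[ok]))
}

#' Per-event one-minute MAP distribution and Gray-Zone fraction
#'
#' For Fig-3-style analyses: positives contribute the mean MAP over the
#' first 60 s of their matched event; negatives contribute the mean MAP over
#' the first 60 s of their prediction window. The Gray-Zone fraction is the
#' share of negative-class values inside `[65, 75]` mmHg, the range where
#' the hypotension diagnosis is most ambiguous. Items whose averaging minute
#' contains masked seconds are dropped and counted.
#'
#' @param datapoints metadata data.frame of a labeled dataset (see
#'   [build_dataset()]), with `patient_id`, `label`, `t_now_s`,
#'   `matched_event_onset_s`.
#' @param map_series_by_patient named list of `map_series`, one per patient.
#' @param config the [window_config()] used during labeling.
#' @param gray_zone `c(lo, hi)` mmHg.
#' @return list with `table` (patient_id, label, mean_map_mmHg,
#'   in_gray_zone), `gray_zone_fraction`, `n_dropped`.
#' @export
event_map_distribution <- function(datapoints, map_series_by_patient,
                                   config = window_config(),
                                   gray_zone = c(65, 75)) {
  rows <- list()
  dropped <- 0L
  for (i in seq_len(nrow(datapoints))) {
    p <- datapoints$patient_id[i]
    ms <- map_series_by_patient[[p]]
    if (is.null(ms)) stop("no MAP series for patient ", p)
    t0 <- if (datapoints$label[i] == "positive") {
      datapoints$matched_event_onset_s[i]
    } else {
      datapoints$t_now_s[i] + config$observation_s
    }
    idx <- which(ms$start_time_s + seq_along(ms$values) - 1 >= t0 &
                   ms$start_time_s + seq_along(ms$values) - 1 < t0 + 60)
    if (length(idx) < 60 || any(!ms$valid_mask[idx])) {
      dropped <- dropped + 1L
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = p, label = datapoints$label[i],
      mean_map_mmHg = mean(ms$values[idx]), stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(0), label = character(0),
               mean_map_mmHg = numeric(0))
  tab$in_gray_zone <- tab$mean_map_mmHg >= gray_zone[1] &
    tab$mean_map_mmHg <= gray_zone[2]
  neg <- tab$label == "negative"
  list(table = tab,
       gray_zone_fraction = if (any(neg)) mean(tab$in_gray_zone[neg]) else NA_real_,
       n_dropped = dropped)
}
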