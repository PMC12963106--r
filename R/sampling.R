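#' Window-framing configuration
#'
#' The framing anchors three consecutive windows at each candidate time
#' `t_now`: an 80 s observation window (whose final `extraction_s` seconds
#' are the model input), a 300 s prediction window, and a 60 s slack window
#' that filters near-onset ambiguity. Candidate times advance by
#' exponentially distributed inter-sample intervals with mean
#' `mean_interval_s` (rate 1/3 per minute), clipped to
#' `[interval_floor_s, interval_cap_s]`.
#'
#' @param observation_s observation window length, seconds.
#' @param extraction_s extracted segment length, seconds.
#' @param prediction_s prediction window length, seconds.
#' @param slack_s slack window length, seconds.
#' @param mean_interval_s mean of the exponential inter-sample interval.
#' @param interval_cap_s upper clip of the interval (3 min).
#' @param interval_floor_s lower clip of the interval.
#' @return an object of class `window_config`.
#' @export
window_config <- function(observation_s = 80, extraction_s = 20,
                          prediction_s = 300, slack_s = 60,
                          mean_interval_s = 180, interval_cap_s = 180,
                          interval_floor_s = 0) {
  stopifnot(extraction_s <= observation_s, observation_s > 0,
            prediction_s > 0, slack_s > 0, mean_interval_s > 0,
            interval_floor_s <= interval_cap_s)
  structure(list(observation_s = observation_s, extraction_s = extraction_s,
                 prediction_s = prediction_s, slack_s = slack_s,
                 mean_interval_s = mean_interval_s,
                 interval_cap_s = interval_cap_s,
                 interval_floor_s = interval_floor_s),
            class = "window_config")
}

# Total frame length: observation + prediction + slack (440 s by default).
frame_length_s <- function(config) {
  config$observation_s + config$prediction_s + config$slack_s
}

#' Draw candidate times from the clipped-exponential renewal process
#'
#' Starting at the record beginning, successive candidate times advance by
#' independent exponential intervals (mean `mean_interval_s`) clipped to
#' `[interval_floor_s, interval_cap_s]`. Only candidates whose full frame
#' (observation + prediction + slack) fits in the record are returned.
#'
#' @param record_duration_s record length, seconds.
#' @param config a [window_config()].
#' @param seed integer seed (deterministic draws).
#' @return numeric vector of candidate `t_now` values in seconds.
#' @export
draw_time_points <- function(record_duration_s, config = window_config(),
                             seed = 1L) {
  frame <- frame_length_s(config)
  if (record_duration_s <= frame) return(numeric(0))
  with_seed(seed, {
    # Upper bound on the number of draws needed, then cumulate.
    n_max <- ceiling(record_duration_s / max(1e-9, max(config$interval_floor_s, 1))) + 10L
    n_max <- min(n_max, ceiling(record_duration_s) + 10L)
    gaps <- pmin(pmax(stats::rexp(n_max, rate = 1 / config$mean_interval_s),
                      config$interval_floor_s), config$interval_cap_s)
    tt <- cumsum(gaps)
    tt[tt + frame <= record_duration_s]
  })
}

#' Label one candidate time against a patient's event list
#'
#' Decision procedure, evaluated in order on the half-open windows anchored
#' at `t_now` (observation `[t, t+80)`, prediction `[t+80, t+380)`, slack
#' `[t+380, t+440)` under defaults):
#' 1. any event interval intersecting the observation window -> skip
#'    `event_in_observation` (the record already shows hypotension);
#' 2. any event onset inside the prediction window -> `positive`, anchored
#'    to the earliest such onset;
#' 3. any event onset inside the slack window -> skip `event_in_slack`
#'    (near-onset ambiguity);
#' 4. otherwise `negative`.
#'
#' @param t_now_s candidate time, seconds.
#' @param events ordered, disjoint events data.frame (`onset_s`,
#'   `offset_s`).
#' @param config a [window_config()].
#' @return list with `label` (one of `positive`, `negative`,
#'   `event_in_observation`, `event_in_slack`) and `matched_event_onset_s`
#'   (earliest qualifying onset for positives, else `NA`).
#' @export
frame_and_label <- function(t_now_s, events, config = window_config()) {
  obs_end <- t_now_s + config$observation_s
  pred_end <- obs_end + config$prediction_s
  slack_end <- pred_end + config$slack_s
  if (nrow(events) > 0) {
    if (any(events$onset_s < obs_end & events$offset_s > t_now_s)) {
      return(list(label = "event_in_observation", matched_event_onset_s = NA_real_))
    }
    in_pred <- events$onset_s >= obs_end & events$onset_s < pred_end
    if (any(in_pred)) {
      return(list(label = "positive",
                  matched_event_onset_s = min(events$onset_s[in_pred])))
    }
    if (any(events$onset_s >= pred_end & events$onset_s < slack_end)) {
      return(list(label = "event_in_slack", matched_event_onset_s = NA_real_))
    }
  }
  list(label = "negative", matched_event_onset_s = NA_real_)
}

#' Extract the 20-second model-input segment at a candidate time
#'
#' The extraction zone is the final `extraction_s` seconds of the
#' observation window, `[t_now + 60, t_now + 80)` under defaults. The
#' segment is the raw 125 Hz samples of that zone (length 2500); its
#' summary statistic `segment_mean_map` is the mean of the per-beat MAPs of
#' valid beats overlapping the zone. The extraction is refused
#' (`poor_quality`) when the zone extends past the record or when less than
#' `min_coverage` of it is covered by valid beats.
#'
#' @param waveform canonical 125 Hz `abp_waveform`.
#' @param beats flagged beats data.frame.
#' @param t_now_s candidate time, seconds.
#' @param config a [window_config()].
#' @param min_coverage minimum fraction of the zone covered by valid beats.
#' @return list with `segment` (numeric, `extraction_s * 125` samples) and
#'   `segment_mean_map` — or the string `"poor_quality"`.
#' @export
extract_segment <- function(waveform, beats, t_now_s, config = window_config(),
                            min_coverage = 0.95) {
  fs <- waveform$fs
  stopifnot(fs == 125)
  z0 <- t_now_s + config$observation_s - config$extraction_s
  z1 <- t_now_s + config$observation_s
  i0 <- as.integer(round((z0 - waveform$start_time_s) * fs)) + 1L
  n_seg <- as.integer(round(config$extraction_s * fs))
  if (i0 < 1 || i0 + n_seg - 1 > length(waveform$samples)) return("poor_quality")

  vb <- beats[beats$valid, , drop = FALSE]
  if (nrow(vb) == 0) return("poor_quality")
  b0 <- vb$onset_s
  b1 <- vb$onset_s + vb$period_s
  overlap <- pmin(b1, z1) - pmax(b0, z0)
  ov <- overlap > 0
  coverage <- sum(overlap[ov]) / (z1 - z0)
  if (coverage < min_coverage) return("poor_quality")
  list(segment = waveform$samples[i0:(i0 + n_seg - 1L)],
       segment_mean_map = mean(vb$map_mmHg[ov]))
}

#' Build a labeled dataset from preprocessed patients
#'
#' Applies the full data-point selection pipeline per patient: the
#' >= 90 percent clean-data inclusion filter, event detection on the MAP
#' series, Poisson-window candidate drawing, the framing/labeling decision
#' procedure and segment extraction. Skipped candidates are tallied in the
#' provenance. Per-patient randomness uses substreams of `seed`, so the
#' result is reproducible and independent of patient order evaluation.
#'
#' @param patients list of preprocessed patients from
#'   [preprocess_patient()].
#' @param config a [window_config()].
#' @param seed master seed.
#' @param min_clean_fraction patient-inclusion threshold.
#' @param events_by_patient optional named list of precomputed event tables
#'   (defaults to [detect_events()] on each patient's MAP series).
#' @return object of class `ioh_dataset`: list with `meta` (data.frame:
#'   `patient_id`, `t_now_s`, `label`, `segment_mean_map`,
#'   `matched_event_onset_s`, `augmented`), `segments` (matrix, one row per
#'   point), and `provenance` (skip tallies, seed, config, excluded
#'   patients).
#' @export
build_dataset <- function(patients, config = window_config(), seed = 1L,
                          min_clean_fraction = 0.90, events_by_patient = NULL) {
  eligible <- vapply(patients, function(p) p$clean_fraction >= min_clean_fraction,
                     logical(1))
  if (!any(eligible)) stop("zero eligible patients after clean-data filter")
  skips <- c(event_in_observation = 0L, event_in_slack = 0L, poor_quality = 0L)
  meta <- list()
  segs <- list()
  for (i in which(eligible)) {
    p <- patients[[i]]
    ev <- if (!is.null(events_by_patient)) events_by_patient[[p$patient_id]]
          else detect_events(p$map_series)
    tts <- draw_time_points(p$duration_s, config, substream_seed(seed, i))
    for (t_now in tts) {
      lab <- frame_and_label(t_now, ev, config)
      if (lab$label %in% c("event_in_observation", "event_in_slack")) {
        skips[lab$label] <- skips[lab$label] + 1L
        next
      }
      seg <- extract_segment(p$waveform, p$beats, t_now, config)
      if (identical(seg, "poor_quality")) {
        skips["poor_quality"] <- skips["poor_quality"] + 1L
        next
      }
      meta[[length(meta) + 1L]] <- data.frame(
        patient_id = p$patient_id, t_now_s = t_now, label = lab$label,
        segment_mean_map = seg$segment_mean_map,
        matched_event_onset_s = lab$matched_event_onset_s,
        augmented = FALSE, stringsAsFactors = FALSE)
      segs[[length(segs) + 1L]] <- seg$segment
    }
  }
  meta_df <- if (length(meta)) do.call(rbind, meta) else
    data.frame(patient_id = character(0), t_now_s = numeric(0),
               label = character(0), segment_mean_map = numeric(0),
               matched_event_onset_s = numeric(0), augmented = logical(0))
  structure(list(
    meta = meta_df,
    segments = if (length(segs)) do.call(rbind, segs) else
      matrix(numeric(0), 0, 0),
    provenance = list(seed = seed, config = unclass(config),
                      skips = skips,
                      n_patients = length(patients),
                      excluded_patients = vapply(
                        patients[!eligible], function(p) p$patient_id,
                        character(1)))),
    class = "ioh_dataset")
}

#' @export
print.ioh_dataset <- function(x, ...) {
  tab <- table(x$meta$label)
  cat(sprintf("<ioh_dataset> %d points (%s) from %d patients\n",
              nrow(x$meta),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              length(unique(x$meta$patient_id))))
  invisible(x)
}

#' Class-separation statistic of a labeled dataset
#'
#' Delta-mean: the mean segment MAP of negative data points minus the mean
#' segment MAP of positive data points. Typically positive, since segments
#' preceding hypotension sit at lower pressures.
#'
#' @param dataset an `ioh_dataset`.
#' @return delta-mean in mmHg.
#' @export
delta_mean <- function(dataset) {
  lab <- dataset$meta$label
  if (!any(lab == "positive") || !any(lab == "negative")) {
    stop("undefined delta-mean: a class is absent")
  }
  mean(dataset$meta$segment_mean_map[lab == "negative"]) -
    mean(dataset$meta$segment_mean_map[lab == "positive"])
}

#' Augment the positive class by small backward time shifts
#'
#' Each positive data point gains one extra segment per shift in `shifts_s`
#' (small negative offsets of `t_now`), provided the shifted candidate
#' re-labels as positive under the full decision procedure and its shifted
#' extraction zone passes the quality rule. Negatives are untouched;
#' augmented points inherit their parent's `patient_id`, preserving
#' patient-grouped fold integrity. Shifts that violate the window
#' constraints are silently skipped for that point.
#'
#' @param dataset an `ioh_dataset` from [build_dataset()].
#' @param patients the same preprocessed patient list the dataset was built
#'   from (needed to re-extract shifted segments).
#' @param shifts_s numeric vector of time shifts, seconds (default
#'   `c(-10, -5)`).
#' @param config the [window_config()] used for the dataset.
#' @param events_by_patient optional precomputed event tables.
#' @return the augmented `ioh_dataset`.
#' @export
augment_positives <- function(dataset, patients, shifts_s = c(-10, -5),
                              config = window_config(),
                              events_by_patient = NULL) {
  if (length(shifts_s) == 0) return(dataset)
  pat_by_id <- stats::setNames(patients, vapply(patients, function(p) p$patient_id,
                                                character(1)))
  pos_idx <- which(dataset$meta$label == "positive" & !dataset$meta$augmented)
  new_meta <- list()
  new_segs <- list()
  for (i in pos_idx) {
    pid <- dataset$meta$patient_id[i]
    p <- pat_by_id[[pid]]
    if (is.null(p)) stop("patient ", pid, " not found in patient list")
    ev <- if (!is.null(events_by_patient)) events_by_patient[[pid]]
          else detect_events(p$map_series)
    for (s in shifts_s) {
      t_new <- dataset$meta$t_now_s[i] + s
      if (t_new < 0) next
      lab <- frame_and_label(t_new, ev, config)
      if (lab$label != "positive") next
      seg <- extract_segment(p$waveform, p$beats, t_new, config)
      if (identical(seg, "poor_quality")) next
      new_meta[[length(new_meta) + 1L]] <- data.frame(
        patient_id = pid, t_now_s = t_new, label = "positive",
        segment_mean_map = seg$segment_mean_map,
        matched_event_onset_s = lab$matched_event_onset_s,
        augmented = TRUE, stringsAsFactors = FALSE)
      new_segs[[length(new_segs) + 1L]] <- seg$segment
    }
  }
  if (length(new_meta)) {
    dataset$meta <- rbind(dataset$meta, do.call(rbind, new_meta))
    dataset$segments <- rbind(dataset$segments, do.call(rbind, new_segs))
  }
  dataset
}

#' Subset an `ioh_dataset` by row index
#'
#' @param dataset an `ioh_dataset`.
#' @param idx integer or logical row index into the dataset's points.
#' @return the subset `ioh_dataset`.
#' @export
dataset_subset <- function(dataset, idx) {
  dataset$meta <- dataset$meta[idx, , drop = FALSE]
  rownames(dataset$meta) <- NULL
  dataset$segments <- dataset$segments[idx, , drop = FALSE]
  dataset
}
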