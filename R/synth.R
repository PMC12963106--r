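#' Configuration for the synthetic ABP generator
#'
#' Describes one simulated patient record: a slowly drifting mean arterial
#' pressure (MAP) trajectory with scripted and/or random hypotensive dips,
#' a pulsatile pressure waveform built on top of it, and optional injected
#' measurement artifacts. All rates are per hour of record; the waveform is
#' generated at `fs` Hz (125 Hz by default, the canonical rate of the
#' pipeline).
#'
#' @param duration_s record length in seconds.
#' @param fs sampling frequency in Hz.
#' @param map_baseline_mmHg baseline MAP around which the trajectory drifts.
#' @param map_drift_sd random-walk scale of the MAP trajectory, in mmHg per
#'   square-root minute (0 disables drift).
#' @param hr_baseline_bpm baseline heart rate.
#' @param hr_sin_amp_bpm amplitude of the slow (5-min period) heart-rate
#'   sinusoid.
#' @param hr_jitter_sd per-beat white heart-rate jitter, bpm.
#' @param pulse_pressure_mmHg systolic-minus-diastolic excursion of each beat.
#' @param dip_rate_per_hour expected number of random hypotensive dips per
#'   hour (Poisson).
#' @param dip_depth_range_mmHg `c(lo, hi)` uniform range of dip depths below
#'   baseline.
#' @param dip_duration_range_s `c(lo, hi)` uniform range of dip plateau
#'   durations in seconds.
#' @param dip_ramp_s linear on/off ramp flanking each dip plateau, seconds.
#' @param artifact_rate_per_hour expected number of injected artifacts per
#'   hour (Poisson); 0 disables random artifacts.
#' @param artifact_duration_range_s uniform range of artifact durations.
#' @param scripted_dips optional `data.frame(onset_s, depth_mmHg, duration_s)`
#'   of deterministic dips (plateau occupies `[onset, onset + duration)`).
#' @param scripted_artifacts optional `data.frame(start_s, duration_s, kind)`
#'   with kind in `square_wave`, `high_frequency_noise`, `flatline`, `spike`.
#' @param seed integer seed; identical configurations generate bit-identical
#'   records.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(duration_s = 3600, fs = 125,
                         map_baseline_mmHg = 80, map_drift_sd = 1,
                         hr_baseline_bpm = 70, hr_sin_amp_bpm = 3,
                         hr_jitter_sd = 2,
                         pulse_pressure_mmHg = 50,
                         dip_rate_per_hour = 2,
                         dip_depth_range_mmHg = c(15, 30),
                         dip_duration_range_s = c(90, 240),
                         dip_ramp_s = 10,
                         artifact_rate_per_hour = 0,
                         artifact_duration_range_s = c(5, 20),
                         scripted_dips = NULL,
                         scripted_artifacts = NULL,
                         seed = 1L) {
  stopifnot(fs > 0, duration_s > 0,
            dip_depth_range_mmHg[1] <= dip_depth_range_mmHg[2],
            dip_duration_range_s[1] <= dip_duration_range_s[2],
            dip_rate_per_hour >= 0, artifact_rate_per_hour >= 0,
            hr_baseline_bpm > 0, pulse_pressure_mmHg > 0, dip_ramp_s >= 0)
  cfg <- list(duration_s = duration_s, fs = fs,
              map_baseline_mmHg = map_baseline_mmHg,
              map_drift_sd = map_drift_sd,
              hr_baseline_bpm = hr_baseline_bpm,
              hr_sin_amp_bpm = hr_sin_amp_bpm,
              hr_jitter_sd = hr_jitter_sd,
              pulse_pressure_mmHg = pulse_pressure_mmHg,
              dip_rate_per_hour = dip_rate_per_hour,
              dip_depth_range_mmHg = dip_depth_range_mmHg,
              dip_duration_range_s = dip_duration_range_s,
              dip_ramp_s = dip_ramp_s,
              artifact_rate_per_hour = artifact_rate_per_hour,
              artifact_duration_range_s = artifact_duration_range_s,
              scripted_dips = scripted_dips,
              scripted_artifacts = scripted_artifacts,
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  cfg
}

#' Construct an ABP waveform object
#'
#' @param samples numeric vector of pressure samples in mmHg.
#' @param fs sampling frequency in Hz.
#' @param start_time_s time of the first sample, seconds.
#' @param patient_id opaque patient identifier.
#' @return an object of class `abp_waveform`.
#' @export
abp_waveform <- function(samples, fs, start_time_s = 0, patient_id = "unknown") {
  structure(list(samples = as.numeric(samples), fs = fs,
                 start_time_s = start_time_s, patient_id = patient_id),
            class = "abp_waveform")
}

#' @export
print.abp_waveform <- function(x, ...) {
  cat(sprintf("<abp_waveform> patient %s: %d samples @ %g Hz (%.1f s)\n",
              x$patient_id, length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

# Beat morphology template on phase u in [0, 1): systolic upstroke plus a
# smaller dicrotic bump. Scaled per beat so the sampled mean equals the
# scripted MAP and the peak-to-trough range equals the pulse pressure.
.pulse_template <- function(u) {
  exp(-(u - 0.18)^2 / (2 * 0.05^2)) + 0.35 * exp(-(u - 0.45)^2 / (2 * 0.10^2))
}

# Run-length scan for sub-threshold events on a 1 Hz series with optional
# validity mask; used to derive the generator's ground-truth event list.
.scan_runs <- function(values, valid, threshold, min_len, t0 = 0) {
  below <- valid & !is.na(values) & (values < threshold)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_len
  data.frame(onset_s = t0 + starts[keep] - 1,
             offset_s = t0 + ends[keep])
}

# MAP trajectory at 1 Hz (values at t = 0 .. duration_s - 1): baseline +
# Gaussian random walk + scripted/random dips with linear ramps.
.make_map_trajectory <- function(cfg) {
  n <- as.integer(cfg$duration_s)
  tt <- seq_len(n) - 1
  drift <- if (cfg$map_drift_sd > 0) {
    cumsum(stats::rnorm(n, 0, cfg$map_drift_sd / sqrt(60)))
  } else rep(0, n)
  map <- cfg$map_baseline_mmHg + drift

  dips <- cfg$scripted_dips
  n_rand <- if (cfg$dip_rate_per_hour > 0) {
    stats::rpois(1, cfg$dip_rate_per_hour * cfg$duration_s / 3600)
  } else 0L
  if (n_rand > 0) {
    rnd <- data.frame(
      onset_s = stats::runif(n_rand, 0, cfg$duration_s),
      depth_mmHg = stats::runif(n_rand, cfg$dip_depth_range_mmHg[1],
                                cfg$dip_depth_range_mmHg[2]),
      duration_s = stats::runif(n_rand, cfg$dip_duration_range_s[1],
                                cfg$dip_duration_range_s[2]))
    dips <- rbind(dips, rnd)
  }
  if (!is.null(dips) && nrow(dips) > 0) {
    for (i in seq_len(nrow(dips))) {
      o <- dips$onset_s[i]; d <- dips$duration_s[i]; dep <- dips$depth_mmHg[i]
      r <- cfg$dip_ramp_s
      w <- rep(0, n)
      w[tt >= o & tt < o + d] <- 1
      if (r > 0) {
        pre <- tt >= o - r & tt < o
        w[pre] <- (tt[pre] - (o - r)) / r
        post <- tt >= o + d & tt < o + d + r
        w[post] <- 1 - (tt[post] - (o + d)) / r
      }
      map <- map - dep * w
    }
  }
  map
}

#' Simulate one patient's ABP record with ground truth
#'
#' Generates a 125 Hz (configurable) pulsatile arterial pressure waveform on
#' top of a scripted 1 Hz MAP trajectory, plus full ground-truth annotations:
#' the MAP trajectory itself, true systolic peak times, true hypotension
#' events (MAP < 65 mmHg sustained for at least 60 s), and any injected
#' artifact intervals. Each beat is drawn from a fixed two-bump morphology
#' template rescaled so its sampled mean equals the scripted MAP at the beat
#' midpoint and its peak-to-trough range equals the configured pulse
#' pressure.
#'
#' @param config a [synth_config()].
#' @param patient_id identifier stored on the waveform.
#' @return a list with elements `waveform` (class `abp_waveform`) and `truth`
#'   (list: `true_map` 1 Hz numeric, `true_beat_times` systolic peak times in
#'   seconds, `true_events` data.frame `onset_s`/`offset_s`,
#'   `artifact_intervals` data.frame `start_s`/`end_s`/`kind`).
#' @export
simulate_patient <- function(config, patient_id = "synthetic-1") {
  stopifnot(inherits(config, "synth_config"))
  if (config$duration_s < 60 / config$hr_baseline_bpm) {
    stop("degenerate duration: record shorter than one beat period")
  }
  with_seed(config$seed, {
    map_traj <- .make_map_trajectory(config)

    # Beat onset times: integrate instantaneous heart rate.
    onsets <- numeric(0)
    t <- 0
    hr_fun <- function(t) {
      config$hr_baseline_bpm +
        config$hr_sin_amp_bpm * sin(2 * pi * t / 300)
    }
    while (t < config$duration_s) {
      onsets <- c(onsets, t)
      hr <- hr_fun(t) + stats::rnorm(1, 0, config$hr_jitter_sd)
      period <- min(3, max(0.3, 60 / max(20, hr)))
      t <- t + period
    }

    n_samp <- as.integer(round(config$duration_s * config$fs))
    ts <- (seq_len(n_samp) - 1) / config$fs
    samples <- numeric(n_samp)
    # Pad with a virtual onset so the tail of the record is still pulsatile.
    k <- length(onsets)
    onset_ext <- c(onsets, config$duration_s + (if (k > 1) onsets[k] - onsets[k - 1] else 0.8))
    # First sample index at or after each onset; beat i owns [i0[i], i0[i+1]).
    i0 <- pmin(n_samp + 1L, as.integer(ceiling(onset_ext * config$fs - 1e-9)) + 1L)
    map_mid <- stats::approx(x = seq_along(map_traj) - 1, y = map_traj,
                             xout = pmin(onset_ext[-length(onset_ext)] +
                                           diff(onset_ext) / 2,
                                         length(map_traj) - 1),
                             rule = 2)$y
    peak_times <- numeric(k)
    for (i in seq_len(k)) {
      if (i0[i] > n_samp || i0[i + 1] <= i0[i]) { peak_times[i] <- NA_real_; next }
      idx <- i0[i]:(min(i0[i + 1], n_samp + 1L) - 1L)
      T_i <- onset_ext[i + 1] - onset_ext[i]
      u <- (ts[idx] - onset_ext[i]) / T_i
      v <- .pulse_template(u)
      rng <- max(v) - min(v)
      if (rng < 1e-9) rng <- 1
      samples[idx] <- map_mid[i] + (v - mean(v)) / rng * config$pulse_pressure_mmHg
      peak_times[i] <- ts[idx[which.max(v)]]
    }
    peak_times <- peak_times[!is.na(peak_times)]

    truth <- list(
      true_map = map_traj,
      true_beat_times = peak_times,
      true_events = .scan_runs(map_traj, rep(TRUE, length(map_traj)),
                               threshold = 65, min_len = 60),
      artifact_intervals = merge_intervals(NULL))

    wf <- abp_waveform(samples, config$fs, 0, patient_id)
    if (config$artifact_rate_per_hour > 0 || !is.null(config$scripted_artifacts)) {
      inj <- .inject_artifacts_impl(wf, truth, config)
      wf <- inj$waveform; truth <- inj$truth
    }
    list(waveform = wf, truth = truth)
  })
}

.artifact_kinds <- c("square_wave", "high_frequency_noise", "flatline", "spike")

# Applies artifact corruption under the caller's RNG state.
.inject_artifacts_impl <- function(waveform, truth, config) {
  dur <- length(waveform$samples) / waveform$fs
  sched <- config$scripted_artifacts
  n_rand <- if (config$artifact_rate_per_hour > 0) {
    stats::rpois(1, config$artifact_rate_per_hour * dur / 3600)
  } else 0L
  if (n_rand > 0) {
    rnd <- data.frame(
      start_s = stats::runif(n_rand, 0, max(0, dur - config$artifact_duration_range_s[2])),
      duration_s = stats::runif(n_rand, config$artifact_duration_range_s[1],
                                config$artifact_duration_range_s[2]),
      kind = sample(.artifact_kinds, n_rand, replace = TRUE),
      stringsAsFactors = FALSE)
    sched <- rbind(sched, rnd)
  }
  if (is.null(sched) || nrow(sched) == 0) {
    return(list(waveform = waveform, truth = truth))
  }
  stopifnot(all(sched$kind %in% .artifact_kinds))
  iv <- merge_intervals(data.frame(start_s = sched$start_s,
                                   end_s = pmin(dur, sched$start_s + sched$duration_s),
                                   kind = sched$kind,
                                   stringsAsFactors = FALSE))
  x <- waveform$samples
  fs <- waveform$fs
  for (i in seq_len(nrow(iv))) {
    idx <- which((seq_along(x) - 1) / fs >= iv$start_s[i] &
                   (seq_along(x) - 1) / fs < iv$end_s[i])
    if (length(idx) == 0) next
    kind <- strsplit(iv$kind[i], "+", fixed = TRUE)[[1]][1]
    tt <- (idx - 1) / fs - iv$start_s[i]
    if (kind == "square_wave") {
      # Rails outside the physiologic range, as from a fast-flush test.
      x[idx] <- ifelse(floor(tt * 2.5) %% 2 == 0, 310, 5)
    } else if (kind == "high_frequency_noise") {
      x[idx] <- x[idx] + stats::rnorm(length(idx), 0, 30)
    } else if (kind == "flatline") {
      x[idx] <- x[idx[1]]
    } else if (kind == "spike") {
      sp <- idx[seq(1, length(idx), by = as.integer(fs))]
      for (s in sp) {
        j <- s:min(s + 2, idx[length(idx)])
        x[j] <- 330
      }
    }
  }
  truth$artifact_intervals <- merge_intervals(rbind(truth$artifact_intervals, iv))
  waveform$samples <- x
  list(waveform = waveform, truth = truth)
}

#' Inject measurement artifacts into an ABP waveform
#'
#' Corrupts the waveform inside scripted and/or Poisson-scheduled intervals
#' with one of four artifact kinds (`square_wave`, `high_frequency_noise`,
#' `flatline`, `spike`) and records every corrupted interval in the ground
#' truth. Samples outside artifact intervals are untouched; overlapping
#' intervals are merged.
#'
#' @inheritParams simulate_patient
#' @param waveform an `abp_waveform`.
#' @param truth ground-truth list as returned by [simulate_patient()].
#' @return list with updated `waveform` and `truth`.
#' @export
inject_artifacts <- function(waveform, truth, config) {
  with_seed(substream_seed(config$seed, 7L),
            .inject_artifacts_impl(waveform, truth, config))
}

#' Simulate a cohort of patients with steerable class separation
#'
#' Generates `n_patients` records from a shared configuration template,
#' varying baseline MAP and dip frequency across patients so that the
#' class-separation statistic of the downstream labeled dataset (delta-mean:
#' mean segment MAP of negatives minus positives) is steered toward
#' `delta_mean_target`. Half of the cohort is made hypotension-prone (lower
#' baseline, dips at the template rate) and half stable (higher baseline, no
#' dips); the baseline split is scaled so the mixture of negative data points
#' across both groups lands near the requested separation.
#'
#' @param config_template a [synth_config()] shared by the cohort.
#' @param n_patients number of patients (>= 1).
#' @param delta_mean_target desired downstream delta-mean in mmHg, or `NULL`
#'   to replicate the template unchanged.
#' @param seed master seed; per-patient seeds are derived substreams.
#' @return list of per-patient lists `(waveform, truth)`.
#' @export
simulate_cohort <- function(config_template, n_patients, delta_mean_target = NULL,
                            seed = 1L) {
  stopifnot(inherits(config_template, "synth_config"), n_patients >= 1)
  if (!is.null(delta_mean_target) && delta_mean_target < 0) {
    stop("unreachable delta_mean_target: must be >= 0")
  }
  lapply(seq_len(n_patients), function(i) {
    cfg <- config_template
    cfg$seed <- substream_seed(seed, i)
    if (!is.null(delta_mean_target)) {
      # Empirically calibrated: negatives arise from both groups while
      # positives arise almost only from the prone group, so the realized
      # separation is about half the baseline split.
      sep <- 1.58 * delta_mean_target
      if (i %% 2 == 1) {           # hypotension-prone
        cfg$map_baseline_mmHg <- config_template$map_baseline_mmHg - sep / 2
        cfg$dip_rate_per_hour <- max(config_template$dip_rate_per_hour, 3)
      } else {                     # stable
        cfg$map_baseline_mmHg <- config_template$map_baseline_mmHg + sep / 2
        cfg$dip_rate_per_hour <- 0
      }
    }
    simulate_patient(cfg, patient_id = sprintf("P%04d", i))
  })
}
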