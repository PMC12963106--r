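#' Canonical synthetic study conditions
#'
#' The configuration template used by the package's cohort-scale
#' experiments: two-hour intraoperative records at 125 Hz, baseline MAP
#' 80 mmHg with a modest random-walk drift (0.5 mmHg per square-root
#' minute), heart rate around 70 bpm, pulse pressure 50 mmHg, and
#' hypotensive dips of 15-30 mmHg lasting 1.5-4 minutes at three per hour
#' in dip-prone patients. These values sit inside the ranges reported for
#' real surgical cohorts (mean MAP in the high 70s to low 80s, a handful
#' of hypotension events per patient, events a few minutes long).
#'
#' @param duration_s record length per patient, seconds.
#' @return a [synth_config()] template.
#' @export
synthetic_study_template <- function(duration_s = 7200) {
  synth_config(duration_s = duration_s, fs = 125,
               map_baseline_mmHg = 80, map_drift_sd = 0.5,
               hr_baseline_bpm = 70, hr_sin_amp_bpm = 3, hr_jitter_sd = 2,
               pulse_pressure_mmHg = 50,
               dip_rate_per_hour = 3,
               dip_depth_range_mmHg = c(15, 30),
               dip_duration_range_s = c(90, 240))
}

#' Simulate, preprocess and label a full synthetic study
#'
#' Runs the whole pipeline under the canonical study conditions: cohort
#' simulation with steerable class separation, beat detection and quality
#' control, the clean-data patient filter, hypotension event detection and
#' Poisson-window data-point labeling.
#'
#' @param n_patients cohort size.
#' @param delta_mean_target downstream class-separation target, mmHg.
#' @param seed master seed for both simulation and labeling.
#' @param duration_s record length per patient, seconds.
#' @return list with `patients` (preprocessed), `dataset` (`ioh_dataset`),
#'   and `truths` (per-patient ground-truth annotations, named by patient).
#' @export
build_synthetic_study <- function(n_patients = 100, delta_mean_target = 12,
                                  seed = 1L, duration_s = 7200) {
  tpl <- synthetic_study_template(duration_s)
  cohort <- simulate_cohort(tpl, n_patients, delta_mean_target, seed = seed)
  patients <- lapply(cohort, function(p) preprocess_patient(p$waveform))
  truths <- stats::setNames(lapply(cohort, function(p) p$truth),
                            vapply(patients, function(p) p$patient_id,
                                   character(1)))
  dataset <- build_dataset(patients, window_config(),
                           seed = substream_seed(seed, 999L))
  list(patients = patients, dataset = dataset, truths = truths)
}
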