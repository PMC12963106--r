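# Shared fixtures, built in code and cached for the duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A clean one-hour patient (no artifacts, mild drift, a few dips).
clean_patient <- function() cached("clean_patient", {
  cfg <- synth_config(duration_s = 3600, seed = 301, map_drift_sd = 0.5,
                      dip_rate_per_hour = 3)
  p <- simulate_patient(cfg, "clean-1")
  c(p, list(prep = preprocess_patient(p$waveform)))
})

# Small cohort (steered separation) shared by sampling/evaluation tests.
small_study <- function() cached("small_study", {
  build_synthetic_study(n_patients = 16, delta_mean_target = 12, seed = 401,
                        duration_s = 3600)
})

# Large cohort for the standardization experiment (about 5,000 points).
large_study <- function() cached("large_study", {
  build_synthetic_study(n_patients = 100, delta_mean_target = 12, seed = 501,
                        duration_s = 7200)
})

# Separable toy dataset of pulse-like segments: positives around 60 mmHg,
# negatives around 90 mmHg, pulsatile with phase jitter and noise.
make_toy_dataset <- function(n, len = 2500, seed = 1, n_patients = 20,
                             prefix = "T", sep_sd = 3, shuffle_labels = FALSE) {
  withr::with_seed(seed, {
    y <- rep(0:1, length.out = n)
    m <- ifelse(y == 1, 60, 90) + rnorm(n, 0, sep_sd)
    tt <- (0:(len - 1)) / 125
    segs <- t(vapply(seq_len(n), function(i) {
      m[i] + 20 * sin(2 * pi * 1.2 * tt + runif(1, 0, 6)) + rnorm(len, 0, 1)
    }, numeric(len)))
    if (shuffle_labels) y <- sample(y)
    structure(list(
      meta = data.frame(
        patient_id = paste0(prefix, rep(seq_len(n_patients), length.out = n)),
        t_now_s = seq_len(n) * 200,
        label = ifelse(y == 1, "positive", "negative"),
        segment_mean_map = m,
        matched_event_onset_s = NA_real_,
        augmented = FALSE,
        stringsAsFactors = FALSE),
      segments = segs,
      provenance = list(seed = seed)), class = "ioh_dataset")
  })
}
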