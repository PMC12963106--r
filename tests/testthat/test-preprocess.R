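test_that("Fourier resampling preserves constants, tones, and is identity at 125 Hz", {
  const <- abp_waveform(rep(80, 2000), fs = 500)
  out <- resample_to_125(const)
  expect_equal(out$fs, 125)
  expect_length(out$samples, 500)
  expect_true(all(abs(out$samples - 80) < 1e-9))

  tt <- (0:3999) / 500
  tone <- abp_waveform(80 + 10 * sin(2 * pi * 1 * tt), fs = 500)
  res <- resample_to_125(tone)
  expect_length(res$samples, 1000)
  sp <- Mod(stats::fft(res$samples - mean(res$samples)))[2:500]
  f_axis <- (1:499) * 125 / 1000
  f_peak <- f_axis[which.max(sp)]
  amp <- 2 * max(sp) / 1000
  expect_lt(abs(f_peak - 1) / 1, 0.01)
  expect_lt(abs(amp - 10) / 10, 0.01)

  already <- abp_waveform(rnorm(1000, 80), fs = 125)
  expect_identical(resample_to_125(already)$samples, already$samples)
  expect_error(resample_to_125(abp_waveform(rep(80, 100), fs = 100)),
               "upsampling")
})

test_that("beat detection: none on flatlines, accurate counts and peaks on clean records", {
  flat <- abp_waveform(rep(80, 60 * 125), fs = 125)
  expect_equal(nrow(detect_beats(flat)), 0)

  cfg <- synth_config(duration_s = 60, hr_baseline_bpm = 60, hr_sin_amp_bpm = 0,
                      hr_jitter_sd = 0, map_drift_sd = 0, dip_rate_per_hour = 0,
                      seed = 7)
  p <- simulate_patient(cfg)
  beats <- detect_beats(p$waveform)
  expect_lte(abs(nrow(beats) - 60), 1)
  err <- vapply(beats$systolic_peak_s,
                function(t) min(abs(p$truth$true_beat_times - t)), numeric(1))
  expect_lt(max(err), 0.020)
})

test_that("per-beat MAP recovers the scripted trajectory within 1 mmHg", {
  cp <- clean_patient()
  vb <- cp$prep$beats[cp$prep$beats$valid, ]
  truth_at <- stats::approx(seq_along(cp$truth$true_map) - 1, cp$truth$true_map,
                            vb$onset_s + vb$period_s / 2, rule = 2)$y
  expect_lt(max(abs(vb$map_mmHg - truth_at)), 1)
  # SBP/DBP structure: dbp <= map <= sbp always
  expect_true(all(vb$dbp_mmHg <= vb$map_mmHg & vb$map_mmHg <= vb$sbp_mmHg))
})

test_that("abnormality rules fire on direct rule evaluation", {
  mk <- function(sbp = 120, dbp = 70, map = 88, period = 1, var = 100) {
    data.frame(onset_s = c(0, 1), systolic_peak_s = c(0.2, 1.2),
               diastolic_trough_s = c(0.9, 1.9),
               sbp_mmHg = c(120, sbp), dbp_mmHg = c(70, dbp),
               map_mmHg = c(88, map), period_s = c(1, period),
               var_mmHg2 = c(100, var), valid = TRUE,
               abnormality_codes = "", stringsAsFactors = FALSE)
  }
  f <- function(b) flag_abnormal_beats(b)
  expect_match(f(mk(sbp = 320))$abnormality_codes[2], "sbp_range")
  expect_match(f(mk(dbp = 5, map = 60))$abnormality_codes[2], "dbp_range")
  expect_match(f(mk(sbp = 122, dbp = 115, map = 118))$abnormality_codes[2],
               "pulse_pressure")
  expect_match(f(mk(period = 0.2))$abnormality_codes[2], "period_range")
  expect_match(f(mk(sbp = 145))$abnormality_codes[2], "delta_sbp")
  expect_match(f(mk(period = 1.6))$abnormality_codes[2], "delta_period")
  expect_match(f(mk(var = 0.001))$abnormality_codes[2], "flatline")
  clean <- f(mk())
  expect_true(all(clean$valid))
  expect_true(all(clean$abnormality_codes == ""))
  expect_equal(nrow(flag_abnormal_beats(mk()[0, ])), 0)
})

test_that("beats inside an injected square wave are overwhelmingly flagged", {
  cfg <- synth_config(duration_s = 300, seed = 43, dip_rate_per_hour = 0,
                      map_drift_sd = 0,
                      scripted_artifacts = data.frame(start_s = 120,
                                                      duration_s = 5,
                                                      kind = "square_wave"))
  p <- simulate_patient(cfg)
  beats <- flag_abnormal_beats(detect_beats(p$waveform))
  ov <- beats$onset_s < 125 & (beats$onset_s + beats$period_s) > 120
  expect_gte(sum(ov), 3)
  expect_gte(mean(!beats$valid[ov]), 0.8)
})

test_that("clean fraction equals a brute-force sum over valid periods", {
  cp <- clean_patient()
  beats <- cp$prep$beats
  withr::with_seed(9, beats$valid <- runif(nrow(beats)) > 0.4)
  dur <- cp$prep$duration_s
  expect_equal(clean_fraction(beats, dur),
               min(1, sum(beats$period_s[beats$valid]) / dur))
  all_valid <- beats
  all_valid$valid <- TRUE
  expect_equal(clean_fraction(all_valid, sum(all_valid$period_s)), 1.0)
})

test_that("artifacts never increase the clean fraction", {
  base_cfg <- synth_config(duration_s = 600, seed = 51, dip_rate_per_hour = 0)
  clean <- preprocess_patient(simulate_patient(base_cfg)$waveform)
  art_cfg <- base_cfg
  art_cfg$scripted_artifacts <- data.frame(
    start_s = c(100, 300), duration_s = c(20, 30),
    kind = c("square_wave", "high_frequency_noise"))
  dirty <- preprocess_patient(simulate_patient(art_cfg)$waveform)
  expect_lt(dirty$clean_fraction, clean$clean_fraction)
})

test_that("MAP series interpolates between beats and masks long gaps", {
  mk_beat <- function(onset, map) {
    data.frame(onset_s = onset, systolic_peak_s = onset + 0.2,
               diastolic_trough_s = onset + 0.9, sbp_mmHg = map + 30,
               dbp_mmHg = map - 15, map_mmHg = map, period_s = 1,
               var_mmHg2 = 100, valid = TRUE, abnormality_codes = "",
               stringsAsFactors = FALSE)
  }
  two <- rbind(mk_beat(0, 60), mk_beat(10, 80))
  ms <- beats_to_map_series(two, 16)
  expect_equal(ms$values[6], 70)          # t = 5 s: linear midpoint
  expect_true(all(diff(ms$values[1:11]) > 0))

  gap <- rbind(mk_beat(0, 80), mk_beat(12, 80))
  ms2 <- beats_to_map_series(gap, 13)
  expect_false(any(ms2$valid_mask[7][1]))  # t = 6 s: > 5 s from both beats
  expect_true(ms2$valid_mask[1] && ms2$valid_mask[13])
  expect_true(is.na(ms2$values[7]))

  none <- two[0, ]
  ms3 <- beats_to_map_series(none, 10)
  expect_true(all(!ms3$valid_mask))
})

test_that("preprocessing is idempotent on its own output", {
  cp <- clean_patient()
  again <- resample_to_125(cp$prep$waveform)
  expect_identical(again$samples, cp$prep$waveform$samples)
  reflagged <- flag_abnormal_beats(cp$prep$beats)
  expect_identical(reflagged$valid, cp$prep$beats$valid)
  expect_identical(reflagged$abnormality_codes, cp$prep$beats$abnormality_codes)
})

test_that("beat detection recall and precision exceed 0.99 on artifact-free records", {
  for (seed in c(61, 62)) {
    cfg <- synth_config(duration_s = 1800, seed = seed, map_drift_sd = 1,
                        dip_rate_per_hour = 3)
    p <- simulate_patient(cfg)
    det <- detect_beats(p$waveform)$systolic_peak_s
    tr <- p$truth$true_beat_times
    recall <- mean(vapply(tr, function(t) min(abs(det - t)) <= 0.05, logical(1)))
    precision <- mean(vapply(det, function(t) min(abs(tr - t)) <= 0.05, logical(1)))
    expect_gte(recall, 0.99)
    expect_gte(precision, 0.99)
  }
})

test_that("waveform CSV round-trip preserves samples and sampling rate", {
  cp <- clean_patient()
  wf <- abp_waveform(cp$prep$waveform$samples[1:1250], 125, 0, "rt")
  path <- withr::local_tempfile(fileext = ".csv")
  write_abp_csv(wf, path)
  back <- read_abp_csv(path)
  expect_equal(back$fs, 125)
  expect_equal(back$samples, wf$samples, tolerance = 1e-6)
})
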