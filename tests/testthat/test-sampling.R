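test_that("candidate times are deterministic, bounded, and absent on short records", {
  cfg <- window_config()
  expect_length(draw_time_points(0, cfg, seed = 1), 0)
  expect_length(draw_time_points(400, cfg, seed = 1), 0)  # < 440 s frame
  t1 <- draw_time_points(7200, cfg, seed = 5)
  t2 <- draw_time_points(7200, cfg, seed = 5)
  expect_identical(t1, t2)
  expect_true(all(t1 + 440 <= 7200))
  expect_true(all(diff(t1) <= cfg$interval_cap_s + 1e-9))
})

test_that("candidate counts match a Monte-Carlo clipped-exponential renewal oracle", {
  cfg <- window_config()
  n_rep <- 500
  impl_counts <- vapply(seq_len(n_rep), function(s) {
    length(draw_time_points(7200, cfg, seed = 10000 + s))
  }, numeric(1))
  # Independent renewal simulation with the same clipping rule.
  ora_counts <- withr::with_seed(991, vapply(seq_len(n_rep), function(s) {
    t <- 0; k <- 0
    repeat {
      t <- t + min(max(rexp(1, 1 / 180), 0), 180)
      if (t + 440 > 7200) break
      k <- k + 1
    }
    k
  }, numeric(1)))
  expect_lt(abs(mean(impl_counts) - mean(ora_counts)) / mean(ora_counts), 0.02)
})

test_that("the labeling decision procedure honors its worked boundary cases", {
  ev <- function(onset, offset) data.frame(onset_s = onset, offset_s = offset)
  cfg <- window_config()
  # Onset just past the prediction window (t_now + 6 m 21 s): excluded.
  expect_equal(frame_and_label(100, ev(100 + 381, 100 + 381 + 90), cfg)$label,
               "event_in_slack")
  # Onset inside the prediction window: positive.
  r <- frame_and_label(100, ev(300, 400), cfg)
  expect_equal(r$label, "positive")
  expect_equal(r$matched_event_onset_s, 300)
  # Event already active during the observation window: excluded.
  expect_equal(frame_and_label(100, ev(70, 140), cfg)$label,
               "event_in_observation")
  # Prediction-window boundaries are half-open.
  expect_equal(frame_and_label(0, ev(80, 200), cfg)$label, "positive")
  expect_equal(frame_and_label(0, ev(380, 500), cfg)$label, "event_in_slack")
  expect_equal(frame_and_label(0, ev(440, 600), cfg)$label, "negative")
  # No events at all: negative.
  expect_equal(frame_and_label(100, ev(numeric(0), numeric(0)), cfg)$label,
               "negative")
  # Earliest qualifying onset is matched when several events qualify.
  both <- data.frame(onset_s = c(250, 330), offset_s = c(315, 400))
  expect_equal(frame_and_label(100, both, cfg)$matched_event_onset_s, 250)
})

test_that("labeling agrees with an exhaustive interval oracle on random instances", {
  withr::with_seed(77, {
    mism <- 0L
    for (i in 1:10000) {
      events <- random_event_set()
      t_now <- runif(1, 0, 1600)
      got <- frame_and_label(t_now, events)$label
      want <- oracle_label(t_now, events)
      if (!identical(got, want)) mism <- mism + 1L
    }
    expect_equal(mism, 0L)
  })
})

test_that("segment extraction returns exact-length windows with faithful mean MAP", {
  cp <- clean_patient()
  cfg <- window_config()
  seg <- extract_segment(cp$prep$waveform, cp$prep$beats, 1000, cfg)
  expect_length(seg$segment, 2500)
  truth_zone <- mean(cp$truth$true_map[(1000 + 60):(1000 + 79) + 1])
  expect_lt(abs(seg$segment_mean_map - truth_zone), 1)
  # The segment itself is the raw waveform over the zone.
  i0 <- (1000 + 60) * 125 + 1
  expect_identical(seg$segment, cp$prep$waveform$samples[i0:(i0 + 2499)])

  # Too close to the record end: refused.
  expect_identical(extract_segment(cp$prep$waveform, cp$prep$beats,
                                   cp$prep$duration_s - 10, cfg),
                   "poor_quality")
})

test_that("a flatline across the extraction zone forces a quality skip", {
  cfg <- synth_config(duration_s = 400, seed = 71, dip_rate_per_hour = 0,
                      scripted_artifacts = data.frame(start_s = 150,
                                                      duration_s = 30,
                                                      kind = "flatline"))
  p <- simulate_patient(cfg)
  prep <- preprocess_patient(p$waveform)
  # Zone [t+60, t+80) inside the flatline: t_now = 100 -> zone [160, 180).
  expect_identical(extract_segment(prep$waveform, prep$beats, 100,
                                   window_config()),
                   "poor_quality")
  # Far from the artifact the extraction works.
  expect_type(extract_segment(prep$waveform, prep$beats, 250, window_config()),
              "list")
})

test_that("dataset construction is reproducible and consistent with ground truth", {
  st <- small_study()
  ds <- st$dataset
  expect_gt(nrow(ds$meta), 100)
  expect_true(all(ds$meta$label %in% c("positive", "negative")))

  ds2 <- build_dataset(st$patients, window_config(),
                       seed = ds$provenance$seed)
  expect_identical(ds$meta, ds2$meta)
  expect_identical(ds$segments, ds2$segments)

  # Every positive matches a true event onset of its own patient.
  pos <- ds$meta[ds$meta$label == "positive", ]
  for (i in seq_len(nrow(pos))) {
    tr_on <- st$truths[[pos$patient_id[i]]]$true_events$onset_s
    expect_lte(min(abs(tr_on - pos$matched_event_onset_s[i])), 2)
  }
})

test_that("labels recovered from detected events equal labels from generator truth", {
  st <- small_study()
  cfg <- window_config()
  agree <- 0L; total <- 0L
  boundary_quantized <- logical(0)
  for (p in st$patients) {
    det_ev <- detect_events(p$map_series)
    true_ev <- st$truths[[p$patient_id]]$true_events
    tts <- draw_time_points(p$duration_s, cfg, seed = 123)
    for (t_now in tts) {
      total <- total + 1L
      a <- frame_and_label(t_now, det_ev, cfg)$label
      b <- frame_and_label(t_now, true_ev, cfg)$label
      if (identical(a, b)) {
        agree <- agree + 1L
      } else {
        # The MAP series is a 1 Hz reconstruction, so a detected onset may
        # sit one second off the scripted one; a label can only differ when
        # such an onset coincides with a window edge.
        edges <- t_now + c(cfg$observation_s,
                           cfg$observation_s + cfg$prediction_s,
                           cfg$observation_s + cfg$prediction_s + cfg$slack_s)
        near_edge <- any(vapply(c(det_ev$onset_s, true_ev$onset_s), function(o) {
          min(abs(o - edges)) <= 1.5
        }, logical(1)))
        boundary_quantized <- c(boundary_quantized, near_edge)
      }
    }
  }
  expect_gt(total, 200)
  expect_gte(agree / total, 0.995)
  expect_true(all(boundary_quantized))
})

test_that("no-leakage: extraction zones and negative frames avoid events", {
  st <- small_study()
  for (i in seq_len(nrow(st$dataset$meta))) {
    row <- st$dataset$meta[i, ]
    ev <- st$truths[[row$patient_id]]$true_events
    if (nrow(ev) == 0) next
    z0 <- row$t_now_s + 60; z1 <- row$t_now_s + 80
    expect_false(any(ev$onset_s < z1 & ev$offset_s > z0))
    if (row$label == "negative") {
      expect_false(any(ev$onset_s >= row$t_now_s &
                         ev$onset_s < row$t_now_s + 440))
    }
  }
})

test_that("delta-mean equals a brute-force two-pass difference and errors without both classes", {
  toy <- make_toy_dataset(100, len = 50, seed = 12)
  m <- toy$meta$segment_mean_map
  lab <- toy$meta$label
  expect_equal(delta_mean(toy),
               mean(m[lab == "negative"]) - mean(m[lab == "positive"]))

  toy$meta$segment_mean_map <- ifelse(lab == "negative", 86, 74)
  expect_equal(delta_mean(toy), 12)

  only_neg <- dataset_subset(toy, lab == "negative")
  expect_error(delta_mean(only_neg), "undefined")
})

test_that("positive augmentation preserves labels and never exceeds its bound", {
  st <- small_study()
  ds <- st$dataset
  n_pos <- sum(ds$meta$label == "positive")

  unchanged <- augment_positives(ds, st$patients, shifts_s = numeric(0))
  expect_identical(unchanged$meta, ds$meta)

  aug <- augment_positives(ds, st$patients, shifts_s = c(-5))
  n_pos_aug <- sum(aug$meta$label == "positive")
  expect_lte(n_pos_aug, 2 * n_pos)
  expect_gt(n_pos_aug, n_pos)
  expect_equal(sum(aug$meta$label == "negative"),
               sum(ds$meta$label == "negative"))

  # Re-run every augmented point through the decision procedure.
  added <- aug$meta[aug$meta$augmented, ]
  for (i in seq_len(nrow(added))) {
    p <- Filter(function(q) q$patient_id == added$patient_id[i], st$patients)[[1]]
    relabel <- frame_and_label(added$t_now_s[i], detect_events(p$map_series))
    expect_equal(relabel$label, "positive")
  }
})
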