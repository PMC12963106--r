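# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by the most literal method available (per-second loops,
# pairwise counting, exhaustive interval checks) and never call the package
# code paths they are used to check.

# Run-length scan for sub-threshold events: plain per-second loop.
oracle_detect_events <- function(values, valid, threshold = 65, min_len = 60,
                                 t0 = 0) {
  out <- list()
  run_start <- NA
  for (i in seq_along(values)) {
    below <- valid[i] && !is.na(values[i]) && values[i] < threshold
    if (below && is.na(run_start)) run_start <- i
    if ((!below || i == length(values)) && !is.na(run_start)) {
      run_end <- if (below) i else i - 1
      if (run_end - run_start + 1 >= min_len) {
        out[[length(out) + 1]] <- c(onset = t0 + run_start - 1,
                                    offset = t0 + run_end + 1 - 1)
      }
      run_start <- NA
    }
  }
  if (length(out) == 0) {
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0)))
  }
  m <- do.call(rbind, out)
  data.frame(onset_s = m[, "onset"], offset_s = m[, "offset"])
}

# Per-second accumulation of area under threshold, mmHg*min.
oracle_aut <- function(values, valid, threshold = 65) {
  total <- 0
  for (i in seq_along(values)) {
    if (valid[i] && !is.na(values[i]) && values[i] < threshold) {
      total <- total + (threshold - values[i])
    }
  }
  total / 60
}

# Pairwise Mann-Whitney ROC AUC with half-credit for ties.
oracle_pairwise_auc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# Exhaustive interval logic for the observation/prediction/slack labeling.
oracle_label <- function(t_now, events, obs = 80, pred = 300, slack = 60) {
  if (nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      # event interval [onset, offset) intersects [t_now, t_now + obs)?
      if (max(t_now, events$onset_s[i]) < min(t_now + obs, events$offset_s[i])) {
        return("event_in_observation")
      }
    }
    on <- events$onset_s
    if (any(on >= t_now + obs & on < t_now + obs + pred)) return("positive")
    if (any(on >= t_now + obs + pred & on < t_now + obs + pred + slack)) {
      return("event_in_slack")
    }
  }
  "negative"
}

# Random disjoint ordered event sets on [0, horizon].
random_event_set <- function(horizon = 2000, max_events = 4) {
  k <- sample(0:max_events, 1)
  if (k == 0) {
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0)))
  }
  on <- sort(runif(k, 0, horizon))
  dur <- runif(k, 60, 200)
  off <- on + dur
  keep <- c(TRUE, on[-1] > off[-k])   # drop overlaps
  data.frame(onset_s = on[keep], offset_s = off[keep])
}

# Count pulse maxima by a literal local-maximum scan above a cut level.
oracle_count_pulses <- function(x, level) {
  n <- length(x)
  count <- 0
  i <- 2
  while (i < n) {
    if (x[i] > level && x[i] >= x[i - 1] && x[i] > x[i + 1]) {
      count <- count + 1
      # skip past this crest
      while (i < n && x[i + 1] > level) i <- i + 1
    }
    i <- i + 1
  }
  count
}

# Build a map_series object directly (bypasses beat detection).
make_map_series <- function(values, valid = rep(TRUE, length(values)),
                            start_time_s = 0) {
  v <- as.numeric(values)
  v[!valid] <- NA_real_
  structure(list(values = v, valid_mask = valid, start_time_s = start_time_s),
            class = "map_series")
}
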