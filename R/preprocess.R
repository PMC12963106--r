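#' Resample an ABP waveform to the canonical 125 Hz
#'
#' Fourier-domain resampling: the input spectrum is truncated to the output
#' Nyquist band and inverse-transformed, so spectral content below 62.5 Hz is
#' preserved. Waveforms already at 125 Hz are returned unchanged; upsampling
#' is refused.
#'
#' @param waveform an [abp_waveform()] at `fs >= 125` Hz.
#' @return an `abp_waveform` at 125 Hz with length
#'   `round(n_in * 125 / fs_in)`.
#' @export
resample_to_125 <- function(waveform) {
  stopifnot(inherits(waveform, "abp_waveform"))
  if (waveform$fs == 125) return(waveform)
  if (waveform$fs < 125) stop("upsampling not supported: fs < 125 Hz")
  n_in <- length(waveform$samples)
  n_out <- as.integer(round(n_in * 125 / waveform$fs))
  waveform$samples <- .fft_resample(waveform$samples, n_out)
  waveform$fs <- 125
  waveform
}

# DFT-based resampling to n_out points (keeps the lowest frequencies,
# splitting the Nyquist bin when needed; mirrors the classic FFT resample).
.fft_resample <- function(x, n_out) {
  n_in <- length(x)
  if (n_out == n_in) return(x)
  X <- stats::fft(x)
  Y <- complex(real = rep(0, n_out), imaginary = rep(0, n_out))
  nh <- min(n_in, n_out)
  half <- nh %/% 2
  Y[1:(half + 1)] <- X[1:(half + 1)]
  if (half >= 1) {
    Y[(n_out - half + 1):n_out] <- X[(n_in - half + 1):n_in]
  }
  if (nh %% 2 == 0) {
    # Split the shared Nyquist component symmetrically (downsampling case).
    Y[half + 1] <- Y[half + 1] * 0.5
    Y[n_out - half + 1] <- Y[n_out - half + 1] + Y[half + 1]
  }
  Re(stats::fft(Y, inverse = TRUE)) / n_in
}

#' Default beat-detector parameters
#'
#' The detector convolves the waveform with a first-derivative-of-Gaussian
#' kernel, takes the Shannon energy of the normalized derivative, smooths it
#' with a moving-average envelope, and peak-picks with a refractory period.
#' The parameters of the cited envelogram method are not fixed by its users'
#' reports, so standard values are exposed here.
#'
#' @param gauss_sigma_s Gaussian derivative width, seconds.
#' @param envelope_s moving-average envelope window, seconds.
#' @param refractory_s minimum spacing between detected beats, seconds.
#' @param peak_search_s half-width of the raw-signal search window around an
#'   envelope peak for the systolic peak, seconds.
#' @param envelope_floor fraction of the robust envelope maximum below which
#'   candidate peaks are ignored.
#' @return list of parameters for [detect_beats()].
#' @export
beat_detector_params <- function(gauss_sigma_s = 0.1, envelope_s = 0.12,
                                 refractory_s = 0.3, peak_search_s = 0.15,
                                 envelope_floor = 0.15) {
  list(gauss_sigma_s = gauss_sigma_s, envelope_s = envelope_s,
       refractory_s = refractory_s, peak_search_s = peak_search_s,
       envelope_floor = envelope_floor)
}

# Centered moving average by cumulative sums.
.moving_avg <- function(x, w) {
  w <- max(1L, as.integer(w))
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(0L, seq_len(n) - 1L - (w %/% 2L))
  hi <- pmin(n, seq_len(n) + ((w - 1L) %/% 2L))
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' Detect beats in an ABP waveform
#'
#' Gaussian-derivative filtering followed by a Shannon energy envelogram and
#' refractory peak picking. Each detected beat spans `[onset, next onset)`;
#' its SBP/DBP are the extreme raw samples in that interval and its MAP is
#' the arithmetic mean of the raw samples over the interval. The final
#' (incomplete) beat is dropped. An all-constant input yields zero beats.
#'
#' @param waveform an `abp_waveform` at 125 Hz, at least 2 s long.
#' @param params detector parameters from [beat_detector_params()].
#' @return data.frame with one row per beat: `onset_s`, `systolic_peak_s`,
#'   `diastolic_trough_s`, `sbp_mmHg`, `dbp_mmHg`, `map_mmHg`, `period_s`,
#'   `var_mmHg2` (within-beat sample variance), `valid`, `abnormality_codes`.
#' @export
detect_beats <- function(waveform, params = beat_detector_params()) {
  stopifnot(inherits(waveform, "abp_waveform"), waveform$fs == 125)
  x <- waveform$samples
  fs <- waveform$fs
  n <- length(x)
  empty <- data.frame(onset_s = numeric(0), systolic_peak_s = numeric(0),
                      diastolic_trough_s = numeric(0), sbp_mmHg = numeric(0),
                      dbp_mmHg = numeric(0), map_mmHg = numeric(0),
                      period_s = numeric(0), var_mmHg2 = numeric(0),
                      valid = logical(0), abnormality_codes = character(0),
                      stringsAsFactors = FALSE)
  if (n < 2 * fs) return(empty)

  # First derivative of Gaussian kernel; rectified so only upstrokes carry
  # energy, normalized by a robust maximum so a single artifact cannot
  # rescale the whole record.
  sig <- params$gauss_sigma_s * fs
  half <- ceiling(4 * sig)
  kt <- (-half):half
  kern <- -kt / sig^2 * exp(-kt^2 / (2 * sig^2))
  # Reflect-pad so beats near the record edges keep their upstroke energy.
  pad <- half + 1L
  xp <- c(x[(pad + 1):2], x, x[(n - 1):(n - pad)])
  d <- stats::filter(xp, kern, method = "convolution", sides = 2)
  d <- d[(pad + 1):(pad + n)]
  d[is.na(d)] <- 0
  d <- pmax(as.numeric(d), 0)
  dmax <- stats::quantile(d[d > 0], 0.995, names = FALSE, na.rm = TRUE)
  if (!is.finite(dmax) || dmax < 1e-6) return(empty)  # flat record
  dn <- pmin(d / dmax, 1)

  # Shannon energy with floor, then moving-average envelope.
  e <- dn^2
  e[e < 1e-12] <- 1e-12
  se <- -e * log(e)
  env <- .moving_avg(se, round(params$envelope_s * fs))

  # Candidate local maxima above a floor; a candidate must coincide with a
  # strong upstroke (gates out dicrotic bumps), then greedy refractory
  # selection keeps the strongest peak per beat.
  floor_v <- params$envelope_floor * stats::quantile(env, 0.95, names = FALSE)
  is_max <- c(FALSE, diff(env) > 0) & c(diff(env) <= 0, FALSE) & env > floor_v
  cand <- which(is_max)
  hw_g <- as.integer(round(params$peak_search_s * fs))
  thr_d <- 0.5 * stats::quantile(dn[dn > 1e-3], 0.95, names = FALSE, na.rm = TRUE)
  strong <- vapply(cand, function(p) {
    a <- max(1L, as.integer(p) - hw_g); b <- min(n, as.integer(p) + hw_g)
    max(dn[a:b]) >= thr_d
  }, logical(1))
  cand <- cand[strong]
  refr <- params$refractory_s * fs
  kept <- integer(0)
  for (p in cand) {
    if (length(kept) == 0 || p - kept[length(kept)] >= refr) {
      kept <- c(kept, p)
    } else if (env[p] > env[kept[length(kept)]]) {
      kept[length(kept)] <- p
    }
  }
  if (length(kept) < 2) return(empty)

  # Systolic peak: locate the strongest upstroke near the envelope peak,
  # then take the raw maximum just after it (the envelope maximum itself
  # sits on the upstroke/dicrotic energy complex and lags the peak).
  hw <- as.integer(round(params$peak_search_s * fs))
  lookback <- as.integer(round(2 * params$refractory_s * fs / 2))
  after <- as.integer(round(0.25 * fs))
  sys_idx <- vapply(kept, function(p) {
    a <- max(1L, as.integer(p) - lookback); b <- min(n, as.integer(p) + hw)
    up <- a + which.max(dn[a:b]) - 1L
    e2 <- min(n, up + after)
    up + which.max(x[up:e2]) - 1L
  }, integer(1))
  sys_idx <- unique(sys_idx)
  if (length(sys_idx) < 2) return(empty)

  # Onset: raw minimum between consecutive systolic peaks; first onset from
  # a look-back of one median inter-peak interval.
  ip <- stats::median(diff(sys_idx))
  onset_idx <- integer(length(sys_idx))
  a0 <- max(1L, sys_idx[1] - as.integer(round(ip)))
  onset_idx[1] <- a0 + which.min(x[a0:sys_idx[1]]) - 1L
  for (i in 2:length(sys_idx)) {
    a <- sys_idx[i - 1]; b <- sys_idx[i]
    onset_idx[i] <- a + which.min(x[a:b]) - 1L
  }

  # Close the final beat at the record end when most of it was captured.
  if (n + 1L - onset_idx[length(onset_idx)] <= 1.5 * ip) {
    onset_idx <- c(onset_idx, n + 1L)
    sys_idx <- c(sys_idx, sys_idx[length(sys_idx)])  # placeholder, trimmed below
  }
  k <- length(onset_idx) - 1L
  sbp <- dbp <- mp <- vr <- dia_t <- numeric(k)
  for (i in seq_len(k)) {
    seg <- x[onset_idx[i]:(onset_idx[i + 1] - 1L)]
    sbp[i] <- max(seg); dbp[i] <- min(seg)
    mp[i] <- mean(seg); vr[i] <- stats::var(seg)
    dia_t[i] <- (onset_idx[i] + which.min(seg) - 2L) / fs
  }
  data.frame(onset_s = (onset_idx[seq_len(k)] - 1) / fs,
             systolic_peak_s = (sys_idx[seq_len(k)] - 1) / fs,
             diastolic_trough_s = dia_t,
             sbp_mmHg = sbp, dbp_mmHg = dbp, map_mmHg = mp,
             period_s = diff(onset_idx) / fs,
             var_mmHg2 = vr,
             valid = TRUE, abnormality_codes = "",
             stringsAsFactors = FALSE)
}

#' Default beat-level signal abnormality rules
#'
#' Thresholds of the classical signal-abnormality-index family used to flag
#' physiologically implausible or artifactual beats. Every threshold is
#' configurable.
#'
#' @param sbp_range,dbp_range,map_range plausible pressure ranges, mmHg.
#' @param min_pulse_pressure minimum SBP-DBP excursion, mmHg.
#' @param period_range plausible beat period range, seconds.
#' @param max_delta_sbp maximum SBP jump between consecutive beats, mmHg.
#' @param max_delta_period maximum period jump between consecutive beats, s.
#' @param flatline_var minimum within-beat sample variance, mmHg^2.
#' @return list of rule thresholds for [flag_abnormal_beats()].
#' @export
abnormality_rules <- function(sbp_range = c(30, 300), dbp_range = c(10, 200),
                              map_range = c(20, 200), min_pulse_pressure = 10,
                              period_range = c(0.3, 3), max_delta_sbp = 20,
                              max_delta_period = 0.5, flatline_var = 0.01) {
  list(sbp_range = sbp_range, dbp_range = dbp_range, map_range = map_range,
       min_pulse_pressure = min_pulse_pressure, period_range = period_range,
       max_delta_sbp = max_delta_sbp, max_delta_period = max_delta_period,
       flatline_var = flatline_var)
}

#' Flag abnormal beats with signal-quality codes
#'
#' Annotates each beat with zero or more abnormality codes (`sbp_range`,
#' `dbp_range`, `map_range`, `pulse_pressure`, `period_range`, `delta_sbp`,
#' `delta_period`, `flatline`) and sets `valid` to `TRUE` iff no code fires.
#' Delta rules compare each beat with its immediate predecessor.
#'
#' @param beats data.frame from [detect_beats()].
#' @param rules thresholds from [abnormality_rules()].
#' @return the beats data.frame with `valid` and `abnormality_codes` updated.
#' @export
flag_abnormal_beats <- function(beats, rules = abnormality_rules()) {
  if (nrow(beats) == 0) return(beats)
  codes <- vector("list", nrow(beats))
  add <- function(mask, code) {
    for (i in which(mask)) codes[[i]] <<- c(codes[[i]], code)
  }
  add(beats$sbp_mmHg < rules$sbp_range[1] | beats$sbp_mmHg > rules$sbp_range[2],
      "sbp_range")
  add(beats$dbp_mmHg < rules$dbp_range[1] | beats$dbp_mmHg > rules$dbp_range[2],
      "dbp_range")
  add(beats$map_mmHg < rules$map_range[1] | beats$map_mmHg > rules$map_range[2],
      "map_range")
  add(beats$sbp_mmHg - beats$dbp_mmHg < rules$min_pulse_pressure,
      "pulse_pressure")
  add(beats$period_s < rules$period_range[1] | beats$period_s > rules$period_range[2],
      "period_range")
  if (nrow(beats) > 1) {
    dsbp <- c(0, abs(diff(beats$sbp_mmHg)))
    dper <- c(0, abs(diff(beats$period_s)))
    add(dsbp > rules$max_delta_sbp, "delta_sbp")
    add(dper > rules$max_delta_period, "delta_period")
  }
  add(beats$var_mmHg2 < rules$flatline_var, "flatline")
  beats$abnormality_codes <- vapply(codes, function(cc) {
    if (is.null(cc)) "" else paste(cc, collapse = ";")
  }, character(1))
  beats$valid <- beats$abnormality_codes == ""
  beats
}

#' Fraction of a record covered by clean beats
#'
#' The patient-inclusion criterion of the pipeline is
#' `clean_fraction >= 0.90`: at least 90 percent of the record must be
#' covered by valid beats.
#'
#' @param beats flagged beats data.frame.
#' @param total_duration_s record duration in seconds (> 0).
#' @return fraction in `[0, 1]`.
#' @export
clean_fraction <- function(beats, total_duration_s) {
  stopifnot(total_duration_s > 0)
  f <- sum(beats$period_s[beats$valid]) / total_duration_s
  min(1, max(0, f))
}

#' Build a 1 Hz MAP series from validated beats
#'
#' Per-beat MAP values of valid beats (anchored at beat onsets) are
#' linearly interpolated onto a 1 Hz grid. Seconds farther than
#' `max_gap_s` from the nearest valid beat anchor are masked invalid; the
#' values at masked positions are a sentinel (`NA`) and are never used by
#' downstream statistics.
#'
#' @param beats flagged beats data.frame.
#' @param duration_s record duration in seconds.
#' @param max_gap_s largest bridgeable distance to a valid beat, seconds.
#' @param start_time_s time of the first second.
#' @return object of class `map_series`: list with `values`, `valid_mask`,
#'   `start_time_s`.
#' @export
beats_to_map_series <- function(beats, duration_s, max_gap_s = 5,
                                start_time_s = 0) {
  n <- as.integer(floor(duration_s))
  tt <- start_time_s + seq_len(n) - 1
  vb <- beats[beats$valid, , drop = FALSE]
  if (nrow(vb) == 0) {
    return(structure(list(values = rep(NA_real_, n),
                          valid_mask = rep(FALSE, n),
                          start_time_s = start_time_s),
                     class = "map_series"))
  }
  anchor <- vb$onset_s
  vals <- stats::approx(anchor, vb$map_mmHg, xout = tt, rule = 2, ties = mean)$y
  # Distance to nearest anchor.
  j <- findInterval(tt, sort(anchor))
  srt <- sort(anchor)
  left <- ifelse(j >= 1, tt - srt[pmax(j, 1)], Inf)
  right <- ifelse(j < length(srt), srt[pmin(j + 1, length(srt))] - tt, Inf)
  dist <- pmin(ifelse(j >= 1, left, Inf), right)
  mask <- dist <= max_gap_s
  vals[!mask] <- NA_real_
  structure(list(values = vals, valid_mask = mask, start_time_s = start_time_s),
            class = "map_series")
}

#' @export
print.map_series <- function(x, ...) {
  cat(sprintf("<map_series> %d s from t=%g, %.1f%% valid\n",
              length(x$values), x$start_time_s, 100 * mean(x$valid_mask)))
  invisible(x)
}

#' Run the full preprocessing chain on one waveform
#'
#' Resamples to 125 Hz if needed, detects and flags beats, computes the
#' clean-data fraction and the 1 Hz MAP series. The result is the
#' per-patient substrate consumed by event detection and data-point
#' sampling.
#'
#' @param waveform an `abp_waveform`.
#' @param detector_params see [beat_detector_params()].
#' @param rules see [abnormality_rules()].
#' @return list with `waveform` (canonical 125 Hz), `beats`, `map_series`,
#'   `clean_fraction`, `duration_s`, `patient_id`.
#' @export
preprocess_patient <- function(waveform, detector_params = beat_detector_params(),
                               rules = abnormality_rules()) {
  wf <- resample_to_125(waveform)
  beats <- flag_abnormal_beats(detect_beats(wf, detector_params), rules)
  dur <- length(wf$samples) / wf$fs
  list(waveform = wf,
       beats = beats,
       map_series = beats_to_map_series(beats, dur, start_time_s = wf$start_time_s),
       clean_fraction = clean_fraction(beats, dur),
       duration_s = dur,
       patient_id = wf$patient_id)
}
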