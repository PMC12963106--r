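#' Patient-grouped, prevalence-stratified cross-validation folds
#'
#' Splits patients (never data points) into `k` folds of roughly
#' 70/10/20 percent train/validation/test. Patients are ordered by their
#' hypotension prevalence (fraction of positive data points, random
#' tie-break) and dealt round-robin into `k` test groups, which stratifies
#' prevalence across folds; each patient appears in exactly one test set.
#' Within each fold the validation set is a systematic (every m-th) draw
#' from the prevalence-ordered remainder.
#'
#' @param dataset an `ioh_dataset`.
#' @param k number of folds.
#' @param fractions `c(train, val, test)` patient fractions (must sum to 1;
#'   test fraction is implied by `k` in the usual rotating scheme).
#' @param seed integer seed.
#' @return list of `k` fold splits, each a list with `fold_id`,
#'   `train_patients`, `val_patients`, `test_patients`.
#' @export
make_folds <- function(dataset, k = 5, fractions = c(0.7, 0.1, 0.2), seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  meta <- dataset$meta
  pats <- unique(meta$patient_id)
  if (length(pats) < k) stop("fewer patients than folds")
  prev <- vapply(pats, function(p) {
    mean(meta$label[meta$patient_id == p] == "positive")
  }, numeric(1))
  with_seed(seed, {
    ord <- order(prev, stats::runif(length(pats)))
    sorted <- pats[ord]
    group <- rep(seq_len(k), length.out = length(sorted))
    lapply(seq_len(k), function(i) {
      test <- sorted[group == i]
      rest <- sorted[group != i]        # prevalence-ordered already
      val_frac <- fractions[2] / (fractions[1] + fractions[2])
      m <- max(2L, round(1 / val_frac))
      val_idx <- seq(((i - 1L) %% m) + 1L, length(rest), by = m)
      val <- rest[val_idx]
      train <- setdiff(rest, val)
      list(fold_id = i, train_patients = train, val_patients = val,
           test_patients = test)
    })
  })
}

.norm_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    as.integer(as.character(labels) == "positive")
  } else {
    as.integer(labels)
  }
}

#' ROC and precision-recall AUC
#'
#' AUC-ROC by the trapezoidal rule over all score thresholds (equivalently
#' the tie-corrected Mann-Whitney statistic); AUC-PR by interpolation-free
#' step integration. Tied scores cross their threshold simultaneously.
#'
#' @param scores numeric risk scores (higher = more positive).
#' @param labels binary labels (`"positive"`/`"negative"`, or 0/1).
#' @return list with `auc_roc`, `auc_pr`, and `curves` (data.frame of
#'   threshold, fpr, tpr, precision, recall).
#' @export
roc_pr_auc <- function(scores, labels) {
  y <- .norm_labels(labels)
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes required for AUC")

  # Tie-corrected Mann-Whitney form of the trapezoidal ROC area.
  r <- rank(scores, ties.method = "average")
  auc_roc <- (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  # Sweep unique thresholds descending; ties grouped.
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]
  ss <- scores[ord]
  grp_last <- which(diff(ss) != 0)
  cut_idx <- c(grp_last, length(ss))
  tp <- cumsum(ys)[cut_idx]
  fp <- cut_idx - tp
  tpr <- tp / n_pos
  fpr <- fp / n_neg
  prec <- tp / (tp + fp)
  d_rec <- diff(c(0, tpr))
  auc_pr <- sum(d_rec * prec)
  list(auc_roc = auc_roc, auc_pr = auc_pr,
       curves = data.frame(threshold = ss[cut_idx], fpr = fpr, tpr = tpr,
                           precision = prec, recall = tpr))
}

#' Classification metrics at the fixed-specificity operating point
#'
#' The decision threshold is the smallest observed score value such that
#' the fraction of negatives scored strictly below it reaches the target
#' specificity (80 percent by default, i.e. a 20 percent false-positive
#' rate); points scoring at or above the threshold are classified positive.
#' All point metrics are evaluated at that threshold on the same score set.
#' When no observed score achieves the target (degenerate ties) the report
#' carries the achieved specificity and a warning flag.
#'
#' @param scores numeric risk scores.
#' @param labels binary labels.
#' @param target_specificity target true-negative rate.
#' @return list with `metrics` (one-row data.frame: auc_roc, auc_pr,
#'   accuracy, sensitivity, specificity, ppv, npv, f1, fpr, brier),
#'   `threshold`, `calibration` (10-bin curve, probability scores only),
#'   `degenerate` flag.
#' @export
operating_point_metrics <- function(scores, labels, target_specificity = 0.80) {
  y <- .norm_labels(labels)
  aucs <- roc_pr_auc(scores, y)
  neg_scores <- scores[y == 0]
  cand <- sort(unique(scores))
  spec_at <- vapply(cand, function(thr) mean(neg_scores < thr), numeric(1))
  ok <- which(spec_at >= target_specificity)
  degenerate <- length(ok) == 0
  if (degenerate) {
    warning("target specificity unreachable on this score set; reporting achieved value")
    thr <- cand[length(cand)]
  } else {
    thr <- cand[ok[1]]
  }
  pred <- as.integer(scores >= thr)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  f1 <- if (!is.na(ppv) && ppv + sens > 0) 2 * ppv * sens / (ppv + sens) else NA_real_
  is_prob <- all(scores >= 0 & scores <= 1)
  brier <- if (is_prob) mean((scores - y)^2) else NA_real_
  calib <- NULL
  if (is_prob) {
    bin <- pmin(floor(scores * 10) + 1, 10)
    calib <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
      data.frame(bin = b, mean_predicted = mean(scores[bin == b]),
                 observed_rate = mean(y[bin == b]), n = sum(bin == b))
    }))
  }
  list(metrics = data.frame(auc_roc = aucs$auc_roc, auc_pr = aucs$auc_pr,
                            accuracy = (tp + tn) / length(y),
                            sensitivity = sens, specificity = spec,
                            ppv = ppv, npv = npv, f1 = f1, fpr = 1 - spec,
                            brier = brier),
       threshold = thr, calibration = calib, degenerate = degenerate)
}

#' Aggregate per-fold metric reports
#'
#' Mean and normal-approximation 95 percent confidence half-width
#' (`1.96 * sd / sqrt(k)`) per metric across folds. A single report yields
#' the mean with an undefined (NA) half-width.
#'
#' @param reports list of reports from [operating_point_metrics()].
#' @return data.frame with one row per metric: `metric`, `mean`,
#'   `ci_halfwidth`.
#' @export
aggregate_folds <- function(reports) {
  stopifnot(length(reports) >= 1)
  tab <- do.call(rbind, lapply(reports, function(r) r$metrics))
  k <- nrow(tab)
  data.frame(
    metric = names(tab),
    mean = vapply(tab, mean, numeric(1)),
    ci_halfwidth = if (k >= 2) {
      vapply(tab, function(x) 1.96 * stats::sd(x) / sqrt(k), numeric(1))
    } else rep(NA_real_, ncol(tab)),
    row.names = NULL)
}

# Internal: split one dataset by patient sets.
.split_by_patients <- function(dataset, patients) {
  dataset_subset(dataset, dataset$meta$patient_id %in% patients)
}

#' Within-dataset patient-grouped cross-validation
#'
#' Runs the trainer on each fold's train/validation patients and evaluates
#' on the fold's test patients, reporting the per-fold AUC-ROC.
#'
#' @param dataset an `ioh_dataset`.
#' @param trainer a trainer function, see [trainer_mapthr()].
#' @param k number of folds.
#' @param seed integer seed.
#' @return numeric vector of per-fold test AUC-ROC values.
#' @export
crossval_auc <- function(dataset, trainer, k = 5, seed = 1L) {
  folds <- make_folds(dataset, k = k, seed = seed)
  vapply(folds, function(f) {
    model <- trainer(.split_by_patients(dataset, f$train_patients),
                     .split_by_patients(dataset, f$val_patients),
                     seed = substream_seed(seed, f$fold_id))
    test <- .split_by_patients(dataset, f$test_patients)
    roc_pr_auc(predict_dataset(model, test), test$meta$label)$auc_roc
  }, numeric(1))
}

#' Cross-dataset train/test AUC matrix
#'
#' The generalizability experiment: diagonal cells are within-dataset
#' `k`-fold patient-grouped cross-validation (mean test AUC-ROC);
#' off-diagonal cells train on the full source dataset (with an internal
#' patient-grouped validation split) and test on the full target dataset.
#' Patient identifiers must be globally unique so no patient can sit on
#' both sides of a cell.
#'
#' @param datasets named list of `ioh_dataset` objects (>= 2).
#' @param trainer trainer function, see [trainer_mapthr()].
#' @param seed integer seed.
#' @param k folds for the diagonal cells.
#' @param val_frac patient fraction held out for validation off-diagonal.
#' @return numeric matrix (train x test) of AUC-ROC values.
#' @export
cross_dataset_matrix <- function(datasets, trainer, seed = 1L, k = 5,
                                 val_frac = 0.125) {
  stopifnot(length(datasets) >= 2, !is.null(names(datasets)))
  all_pats <- lapply(datasets, function(d) unique(d$meta$patient_id))
  for (i in seq_along(datasets)) {
    for (j in seq_along(datasets)) {
      if (i < j && length(intersect(all_pats[[i]], all_pats[[j]])) > 0) {
        stop("patient-id collision between datasets ", names(datasets)[i],
             " and ", names(datasets)[j])
      }
    }
  }
  nd <- length(datasets)
  out <- matrix(NA_real_, nd, nd,
                dimnames = list(train = names(datasets), test = names(datasets)))
  for (i in seq_len(nd)) {
    for (j in seq_len(nd)) {
      if (i == j) {
        out[i, j] <- mean(crossval_auc(datasets[[i]], trainer, k = k,
                                       seed = substream_seed(seed, i)))
      } else {
        src <- datasets[[i]]
        pats <- unique(src$meta$patient_id)
        n_val <- max(1L, round(val_frac * length(pats)))
        val_p <- with_seed(substream_seed(seed, 100 + i),
                           sample(pats, n_val))
        model <- trainer(.split_by_patients(src, setdiff(pats, val_p)),
                         .split_by_patients(src, val_p),
                         seed = substream_seed(seed, 200 + i * nd + j))
        tgt <- datasets[[j]]
        out[i, j] <- roc_pr_auc(predict_dataset(model, tgt),
                                tgt$meta$label)$auc_roc
      }
    }
  }
  out
}

#' Standardize the class separation of a dataset by binned resampling
#'
#' Controls the delta-mean statistic (mean segment MAP of negatives minus
#' positives) of a labeled dataset: data points are binned by segment mean
#' MAP (default 2.5 mmHg bins); all positives are retained and the
#' per-bin negative quotas are reweighted by a one-parameter exponential
#' tilt on the bin index, the parameter found by bisection so that the
#' resampled negative mean lands at `mean(positives) + target_delta`.
#' Sampling within bins is uniform without replacement, so the output is a
#' subset of the input. `mode = "equal_bins"` instead applies the plain
#' equal-per-bin rule (same number of samples from each class in every
#' shared bin), which drives delta-mean toward zero.
#'
#' @param dataset an `ioh_dataset` with both classes present.
#' @param target_delta desired delta-mean, mmHg (>= 0).
#' @param bin_width_mmHg MAP bin width.
#' @param seed integer seed.
#' @param tol acceptable |achieved - target| after resampling, mmHg.
#' @param mode `"tilt"` (default) or `"equal_bins"`.
#' @return the resampled `ioh_dataset`; attributes `achieved_delta` and
#'   `tilt_alpha` record the outcome.
#' @export
standardize_delta_mean <- function(dataset, target_delta, bin_width_mmHg = 2.5,
                                   seed = 1L, tol = 0.25,
                                   mode = c("tilt", "equal_bins")) {
  mode <- match.arg(mode)
  stopifnot(target_delta >= 0)
  meta <- dataset$meta
  if (!any(meta$label == "positive") || !any(meta$label == "negative")) {
    stop("both classes required")
  }
  m <- meta$segment_mean_map
  lo <- floor(min(m) / bin_width_mmHg) * bin_width_mmHg
  hi <- ceiling(max(m) / bin_width_mmHg) * bin_width_mmHg
  breaks <- seq(lo, hi + bin_width_mmHg / 2, by = bin_width_mmHg)
  bin <- findInterval(m, breaks, rightmost.closed = TRUE)

  pos_idx <- which(meta$label == "positive")
  neg_idx <- which(meta$label == "negative")

  if (mode == "equal_bins") {
    keep <- with_seed(seed, {
      unlist(lapply(sort(unique(bin)), function(b) {
        pb <- pos_idx[bin[pos_idx] == b]
        nb <- neg_idx[bin[neg_idx] == b]
        kk <- min(length(pb), length(nb))
        c(if (kk > 0) sample(pb, kk) else integer(0),
          if (kk > 0) sample(nb, kk) else integer(0))
      }))
    })
    out <- dataset_subset(dataset, sort(keep))
    attr(out, "achieved_delta") <- delta_mean(out)
    return(out)
  }

  pos_mean <- mean(m[pos_idx])
  target_neg_mean <- pos_mean + target_delta
  bins_j <- sort(unique(bin[neg_idx]))
  n_j <- vapply(bins_j, function(b) sum(bin[neg_idx] == b), numeric(1))
  m_j <- vapply(bins_j, function(b) mean(m[neg_idx][bin[neg_idx] == b]),
                numeric(1))
  rng <- range(m_j)
  if (target_neg_mean < rng[1] || target_neg_mean > rng[2]) {
    stop(sprintf(
      "infeasible target: achievable delta-mean range is [%.2f, %.2f] mmHg",
      rng[1] - pos_mean, rng[2] - pos_mean))
  }
  neg_mean_at <- function(alpha) {
    w <- n_j * exp(-alpha * seq_along(bins_j))
    sum(w * m_j) / sum(w)
  }
  # neg_mean_at is monotone decreasing in alpha; bisect.
  lo_a <- -50; hi_a <- 50
  for (it in 1:200) {
    mid <- (lo_a + hi_a) / 2
    if (neg_mean_at(mid) > target_neg_mean) lo_a <- mid else hi_a <- mid
  }
  alpha <- (lo_a + hi_a) / 2
  w <- n_j * exp(-alpha * seq_along(bins_j))
  w <- w / sum(w)
  # Largest feasible total without replacement, then largest-remainder
  # rounding of per-bin quotas.
  N <- floor(min(ifelse(w > 1e-12, n_j / w, Inf)))
  N <- min(N, length(neg_idx))
  q_real <- w * N
  q <- floor(q_real)
  rem <- order(q_real - q, decreasing = TRUE)
  short <- N - sum(q)
  if (short > 0) q[rem[seq_len(short)]] <- q[rem[seq_len(short)]] + 1
  q <- pmin(q, n_j)

  keep_neg <- with_seed(seed, {
    unlist(lapply(seq_along(bins_j), function(jj) {
      idx_b <- neg_idx[bin[neg_idx] == bins_j[jj]]
      if (q[jj] >= length(idx_b)) idx_b else sample(idx_b, q[jj])
    }))
  })
  out <- dataset_subset(dataset, sort(c(pos_idx, keep_neg)))
  achieved <- delta_mean(out)
  if (abs(achieved - target_delta) > tol) {
    stop(sprintf(
      "resampling missed the target: achieved %.3f vs target %.3f (tol %.2f); %d negatives kept",
      achieved, target_delta, tol, length(keep_neg)))
  }
  attr(out, "achieved_delta") <- achieved
  attr(out, "tilt_alpha") <- alpha
  out
}

#' Filter a patient roster by demographic criteria
#'
#' Built-in cohort criteria mirror the generalizability experiments:
#' `age_young` (18-55 years inclusive), `age_old` (67+ years; the 56-66
#' band belongs to neither age cohort), `asa_eq_2` (ASA physical-status
#' class 2). A custom predicate function over the roster rows may be given
#' instead.
#'
#' @param patients data.frame with at least `patient_id` plus the fields the
#'   criterion needs (`age`, `asa`).
#' @param criterion one of `"age_young"`, `"age_old"`, `"asa_eq_2"`, or a
#'   function `data.frame -> logical`.
#' @return the filtered patient data.frame.
#' @export
cohort_filter <- function(patients, criterion) {
  need <- function(field) {
    if (!field %in% names(patients)) {
      stop("missing metadata field: ", field)
    }
  }
  keep <- if (is.function(criterion)) {
    criterion(patients)
  } else {
    switch(criterion,
           age_young = { need("age"); patients$age >= 18 & patients$age <= 55 },
           age_old = { need("age"); patients$age >= 67 },
           asa_eq_2 = { need("asa"); patients$asa == 2 },
           stop("unknown criterion: ", criterion))
  }
  patients[keep, , drop = FALSE]
}
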