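test_that("patient-grouped folds are disjoint, exhaustive, and reproducible", {
  toy <- make_toy_dataset(200, len = 50, seed = 21, n_patients = 10)
  folds <- make_folds(toy, k = 5, seed = 3)
  expect_length(folds, 5)
  all_pats <- unique(toy$meta$patient_id)
  test_sets <- lapply(folds, `[[`, "test_patients")
  expect_equal(vapply(test_sets, length, numeric(1)), rep(2, 5))
  expect_setequal(unlist(test_sets), all_pats)
  expect_equal(anyDuplicated(unlist(test_sets)), 0)
  for (f in folds) {
    expect_length(intersect(f$train_patients, f$val_patients), 0)
    expect_length(intersect(f$train_patients, f$test_patients), 0)
    expect_length(intersect(f$val_patients, f$test_patients), 0)
    expect_setequal(c(f$train_patients, f$val_patients, f$test_patients),
                    all_pats)
  }
  expect_identical(folds, make_folds(toy, k = 5, seed = 3))
  expect_error(make_folds(dataset_subset(toy, toy$meta$patient_id %in%
                                           all_pats[1:3]), k = 5),
               "fewer patients")
})

test_that("ROC/PR AUC agree with pairwise and reference implementations", {
  expect_equal(roc_pr_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))$auc_roc,
               1.0)
  withr::with_seed(41, {
    scores <- round(rnorm(400), 1)          # rounding forces ties
    y <- rbinom(400, 1, 0.3)
  })
  r <- roc_pr_auc(scores, y)
  expect_equal(r$auc_roc, oracle_pairwise_auc(scores, y))
  expect_lt(abs(r$auc_roc - 0.5), 0.08)     # labels independent of scores
  ref <- as.numeric(pROC::auc(pROC::roc(y, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(r$auc_roc, ref, tolerance = 1e-12)
  expect_error(roc_pr_auc(scores, rep(1, 400)), "both classes")
})

test_that("ROC AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(42, {
    scores <- rnorm(300)
    y <- rbinom(300, 1, 0.4)
  })
  base <- roc_pr_auc(scores, y)$auc_roc
  expect_equal(roc_pr_auc(exp(scores), y)$auc_roc, base)
  expect_equal(roc_pr_auc(scores^3 + 5 * scores, y)$auc_roc, base)
})

test_that("the operating point pins specificity at the target", {
  # 10 negatives with distinct scores: exactly 8 classified negative.
  scores <- c(1:10, 8.5, 9.5, 10.5)
  y <- c(rep(0, 10), 1, 1, 1)
  rep_ <- operating_point_metrics(scores, y, 0.80)
  expect_equal(rep_$metrics$specificity, 0.8)
  expect_equal(sum(scores[y == 0] < rep_$threshold), 8)
  expect_equal(rep_$metrics$fpr, 1 - rep_$metrics$specificity)
  expect_false(rep_$degenerate)

  # Random scores: every metric equals a brute-force confusion matrix.
  withr::with_seed(43, {
    s2 <- rnorm(500)
    y2 <- rbinom(500, 1, 0.25)
  })
  rp <- operating_point_metrics(s2, y2, 0.80)
  pred <- as.integer(s2 >= rp$threshold)
  tp <- sum(pred & y2); fp <- sum(pred & !y2)
  tn <- sum(!pred & !y2); fn <- sum(!pred & y2)
  expect_equal(rp$metrics$sensitivity, tp / (tp + fn))
  expect_equal(rp$metrics$specificity, tn / (tn + fp))
  expect_equal(rp$metrics$ppv, tp / (tp + fp))
  expect_equal(rp$metrics$npv, tn / (tn + fn))
  expect_equal(rp$metrics$accuracy, (tp + tn) / 500)
  expect_equal(rp$metrics$f1,
               2 * tp / (2 * tp + fp + fn))
  expect_gte(rp$metrics$specificity, 0.80)
  expect_lte(rp$metrics$specificity - 0.80, 1 / sum(y2 == 0))

  # Degenerate all-equal scores carry a warning flag.
  expect_warning(dg <- operating_point_metrics(rep(1, 20),
                                               rep(c(0, 1), 10), 0.8))
  expect_true(dg$degenerate)
})

test_that("probability scores yield Brier and calibration outputs", {
  withr::with_seed(44, {
    p <- runif(300)
    y <- rbinom(300, 1, p)
  })
  rp <- operating_point_metrics(p, y, 0.8)
  expect_equal(rp$metrics$brier, mean((p - y)^2))
  expect_false(is.null(rp$calibration))
  expect_true(all(rp$calibration$observed_rate >= 0 &
                    rp$calibration$observed_rate <= 1))
})

test_that("fold aggregation reproduces hand-computed means and intervals", {
  mk <- function(auc) list(metrics = data.frame(auc_roc = auc, auc_pr = auc,
                                                accuracy = 0.8,
                                                sensitivity = 0.7,
                                                specificity = 0.8, ppv = 0.5,
                                                npv = 0.9, f1 = 0.58,
                                                fpr = 0.2, brier = NA_real_))
  same <- aggregate_folds(list(mk(0.7), mk(0.7), mk(0.7)))
  expect_equal(same$ci_halfwidth[same$metric == "auc_roc"], 0)
  two <- aggregate_folds(list(mk(0.6), mk(0.8)))
  expect_equal(two$mean[two$metric == "auc_roc"], 0.7)
  aucs <- c(0.61, 0.64, 0.59, 0.66, 0.62)
  five <- aggregate_folds(lapply(aucs, mk))
  expect_equal(five$mean[five$metric == "auc_roc"], mean(aucs))
  expect_equal(five$ci_halfwidth[five$metric == "auc_roc"],
               1.96 * sd(aucs) / sqrt(5))
})

test_that("cross-dataset transfer matches within-dataset performance on twins", {
  a <- make_toy_dataset(300, len = 50, seed = 51, n_patients = 15,
                        prefix = "A")
  b <- make_toy_dataset(300, len = 50, seed = 52, n_patients = 15,
                        prefix = "B")
  m <- cross_dataset_matrix(list(a = a, b = b), trainer_mapthr(), seed = 6)
  expect_equal(dim(m), c(2, 2))
  expect_true(all(is.finite(m)))
  expect_lt(max(abs(m[1, 2] - m[1, 1]), abs(m[2, 1] - m[2, 2])), 0.05)

  # Shuffled target labels: chance-level transfer.
  b_null <- make_toy_dataset(300, len = 50, seed = 53, n_patients = 15,
                             prefix = "C", shuffle_labels = TRUE)
  m2 <- cross_dataset_matrix(list(a = a, c = b_null), trainer_mapthr(),
                             seed = 6)
  expect_lt(abs(m2["a", "c"] - 0.5), 0.08)

  collide <- b
  collide$meta$patient_id <- a$meta$patient_id
  expect_error(cross_dataset_matrix(list(a = a, b = collide),
                                    trainer_mapthr(), seed = 1),
               "collision")
})

test_that("delta-mean standardization hits its target and only subsamples", {
  st <- small_study()
  ds <- st$dataset
  natural <- delta_mean(ds)
  expect_gt(natural, 8)

  std <- standardize_delta_mean(ds, 5.01, seed = 9)
  expect_lt(abs(delta_mean(std) - 5.01), 0.25)
  # Subset property: every kept point exists in the input.
  key <- function(d) paste(d$meta$patient_id, d$meta$t_now_s)
  expect_true(all(key(std) %in% key(ds)))
  expect_lte(nrow(std$meta), nrow(ds$meta))
  expect_identical(delta_mean(standardize_delta_mean(ds, 5.01, seed = 9)),
                   delta_mean(std))

  near_zero <- standardize_delta_mean(ds, 0, seed = 9)
  expect_lt(abs(delta_mean(near_zero)), 0.25)

  eq <- standardize_delta_mean(ds, 0, seed = 9, mode = "equal_bins")
  expect_lt(abs(delta_mean(eq)), 1.5)

  expect_error(standardize_delta_mean(ds, 50, seed = 9), "infeasible")
})

test_that("cohort filters respect the age-band and ASA definitions", {
  roster <- data.frame(patient_id = paste0("P", 1:8),
                       age = c(18, 40, 55, 56, 60, 66, 67, 80),
                       asa = c(1, 2, 2, 3, 2, 2, 2, 4))
  young <- cohort_filter(roster, "age_young")
  old <- cohort_filter(roster, "age_old")
  expect_setequal(young$age, c(18, 40, 55))
  expect_setequal(old$age, c(67, 80))
  # 56-66 band belongs to neither cohort.
  expect_false(any(c(56, 60, 66) %in% c(young$age, old$age)))

  both <- cohort_filter(cohort_filter(roster, "age_old"), "asa_eq_2")
  direct <- roster[roster$age >= 67 & roster$asa == 2, ]
  expect_equal(both$patient_id, direct$patient_id)

  expect_equal(nrow(cohort_filter(roster, function(df) df$asa <= 2)), 6)
  expect_error(cohort_filter(roster[, c("patient_id", "age")], "asa_eq_2"),
               "missing metadata field: asa")
})

test_that("within-dataset cross-validation shows the class-separation mechanism", {
  st <- small_study()
  aucs <- crossval_auc(st$dataset, trainer_mapthr(), k = 5, seed = 2)
  expect_length(aucs, 5)
  expect_gt(mean(aucs), 0.7)   # wide separation: threshold model excels
})
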