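test_that("confusion counts tally the four cells", {
  expect_equal(as.list(confusion_counts(c(1, 0, 1), c(1, 0, 1))),
               list(TP = 2L, FP = 0L, TN = 1L, FN = 0L))
  expect_equal(as.list(confusion_counts(c(1, 1, 1, 0, 0, 0),
                                        c(1, 1, 1, 1, 0, 0))),
               list(TP = 3L, FP = 1L, TN = 2L, FN = 0L))
  allwrong <- confusion_counts(c(1, 0), c(0, 1))
  expect_equal(allwrong$TP + allwrong$TN, 0L)
  expect_error(confusion_counts(c(1, 0), c(1)), "length")
  expect_error(confusion_counts(c(1, 2), c(1, 0)), "binary")
})

test_that("Sn/Sp/ACC/MCC match direct evaluation of their formulas", {
  m <- metrics_from_counts(tibble::tibble(TP = 3, FN = 0, TN = 2, FP = 1))
  expect_equal(m$Sn, 1)
  expect_equal(m$Sp, 2 / 3)
  expect_equal(m$ACC, 5 / 6)
  expect_equal(m$MCC, 6 / sqrt(72))

  perfect <- metrics_from_counts(tibble::tibble(TP = 5, FN = 0, TN = 5, FP = 0))
  expect_true(all(unlist(perfect) == 1))

  # zero denominators are undefined (NA), never silently 0
  nopos <- metrics_from_counts(tibble::tibble(TP = 0, FN = 0, TN = 4, FP = 1))
  expect_true(is.na(nopos$Sn))
  expect_true(is.na(nopos$MCC))
  expect_false(is.na(nopos$Sp))
})

test_that("ACC decomposition and label-swap symmetry hold", {
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(4:60, 1)
    truth <- rbinom(n, 1, 0.5)
    pred <- rbinom(n, 1, 0.5)
    if (length(unique(truth)) < 2) next
    cc <- confusion_counts(truth, pred)
    m <- metrics_from_counts(cc)
    P <- cc$TP + cc$FN; N <- cc$TN + cc$FP
    expect_equal(m$ACC * (P + N), m$Sn * P + m$Sp * N, tolerance = 1e-12)
    sw <- metrics_from_counts(confusion_counts(1 - truth, 1 - pred))
    expect_equal(sw$Sn, m$Sp)
    expect_equal(sw$Sp, m$Sn)
    expect_equal(sw$ACC, m$ACC)
    if (!is.na(m$MCC)) expect_equal(abs(sw$MCC), abs(m$MCC))
  }
})

test_that("AUC equals the all-pairs Mann-Whitney count", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.2, 0.1)), 0.75)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  set.seed(8)
  for (rep in 1:15) {
    n <- sample(10:200, 1)
    truth <- c(1, 0, rbinom(n - 2, 1, 0.4))
    score <- sample(round(runif(n), 2))   # rounding forces ties
    expect_equal(roc_auc(truth, score), oracle_auc(truth, score))
  }
  expect_error(roc_auc(rep(1, 4), runif(4)), "both classes")
})

test_that("trapezoidal area under the ROC staircase equals pair-count AUC", {
  set.seed(9)
  for (rep in 1:10) {
    n <- sample(10:120, 1)
    truth <- c(1, 0, rbinom(n - 2, 1, 0.5))
    score <- round(runif(n), 1)
    pts <- roc_points(truth, score)
    expect_equal(pts$fpr[[1]], 0)
    expect_equal(pts$tpr[[nrow(pts)]], 1)
    area <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                   utils::tail(pts$tpr, -1)) / 2)
    expect_equal(area, roc_auc(truth, score), tolerance = 1e-9)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(10)
  truth <- rbinom(80, 1, 0.5)
  score <- runif(80)
  ref <- as.numeric(pROC::auc(pROC::roc(truth, score, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(truth, score), ref, tolerance = 1e-12)
})

test_that("cross-validation pools out-of-fold predictions deterministically", {
  ds <- simulate_psi_dataset(n_pos = 30, n_neg = 30, delta = 1, seed = 2)
  ft <- encode_sequences(ds, "PSTNPss", fit_pstnpss_on_data = TRUE)
  cv1 <- cross_validate(ft, classifier_spec("LR"), folds = 5, seed = 4)
  cv2 <- cross_validate(ft, classifier_spec("LR"), folds = 5, seed = 4)
  expect_identical(cv1$predictions, cv2$predictions)
  expect_equal(cv1$pooled$ACC, 1)     # trivially separable at delta = 1
  expect_equal(nrow(tidy(cv1)), 5)
  expect_true(all(tidy(cv1)$fold == 1:5))
  # pooled report is the metrics of the pooled prediction vector
  p <- cv1$predictions
  expect_equal(cv1$pooled,
               classification_metrics(p$truth, p$estimate, p$prob))
})

test_that("independent_test equals metrics of composed predictions", {
  ds <- simulate_psi_dataset(n_pos = 25, n_neg = 25, delta = 0.9, seed = 6)
  ft <- encode_sequences(ds, "PSTNPss", fit_pstnpss_on_data = TRUE)
  model <- train_stacking(ft, bases = "LR", folds = 3, seed = 1)
  m <- independent_test(model, ft)
  pred <- predict(model, ft)
  expect_equal(m, classification_metrics(ft$label, pred$.pred_class,
                                         pred$.pred_prob))
  expect_error(independent_test(model, ft[0, ]), "non-empty")
})

test_that("percentage formatting scales metric columns by 100", {
  m <- metrics_from_counts(tibble::tibble(TP = 3, FN = 0, TN = 2, FP = 1))
  pct <- metrics_as_percent(m)
  expect_equal(pct$Sp, 66.67)
  expect_equal(pct$ACC, 83.33)
})
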