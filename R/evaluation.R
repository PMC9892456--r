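# Performance metrics: confusion counts, Sn/Sp/ACC/MCC, ROC/AUC by
# Mann-Whitney pair counting, stratified k-fold cross-validation, and
# independent-test evaluation. Undefined metrics (zero denominator) are
# reported as NA, never as 0.

#' Confusion counts
#'
#' @param truth,estimate equal-length binary 0/1 vectors (1 = positive
#'   \eqn{\Psi} class).
#' @return One-row tibble with columns `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(truth, estimate) {
  if (length(truth) != length(estimate)) {
    stop("truth and estimate must have equal length", call. = FALSE)
  }
  truth <- as.integer(truth); estimate <- as.integer(estimate)
  if (!all(truth %in% 0:1) || !all(estimate %in% 0:1)) {
    stop("truth and estimate must be binary 0/1", call. = FALSE)
  }
  tibble::tibble(TP = sum(truth == 1 & estimate == 1),
                 FP = sum(truth == 0 & estimate == 1),
                 TN = sum(truth == 0 & estimate == 0),
                 FN = sum(truth == 1 & estimate == 0))
}

safe_div <- function(num, den) if (den > 0) num / den else NA_real_

#' Metrics from confusion counts
#'
#' Sensitivity `Sn = TP/(TP+FN)`, specificity `Sp = TN/(TN+FP)`, accuracy
#' `ACC = (TP+TN)/n`, and the Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' A metric whose denominator is zero is `NA` (undefined).
#'
#' @param counts one-row tibble from [confusion_counts()].
#' @return One-row tibble `Sn`, `Sp`, `ACC`, `MCC` (fractions, not
#'   percentages).
#' @export
metrics_from_counts <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  mcc_den <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  tibble::tibble(
    Sn = safe_div(TP, TP + FN),
    Sp = safe_div(TN, TN + FP),
    ACC = safe_div(TP + TN, TP + TN + FP + FN),
    MCC = if (mcc_den > 0) (TP * TN - FP * FN) / mcc_den else NA_real_
  )
}

#' Area under the ROC curve by pair counting
#'
#' AUC is the Mann-Whitney statistic: the fraction of
#' (positive, negative) pairs in which the positive scores higher, ties
#' counted as 1/2. Computed via midranks, identical to the all-pairs count.
#'
#' @param truth binary 0/1 vector with both classes present.
#' @param score real classifier scores (higher = more positive).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(truth, score) {
  truth <- as.integer(truth)
  assert_two_classes(truth)
  stopifnot(length(truth) == length(score))
  n_pos <- sum(truth == 1); n_neg <- sum(truth == 0)
  r <- rank(score)   # midranks handle ties as 1/2
  (sum(r[truth == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Empirical ROC curve
#'
#' The staircase traced by sweeping the decision threshold through the
#' observed scores, with 1 - Sp (false-positive rate) as abscissa and Sn
#' (true-positive rate) as ordinate. Tied scores move diagonally, so the
#' trapezoidal area under the curve equals [roc_auc()].
#'
#' @inheritParams roc_auc
#' @return A tibble of class `roc_points` with columns `fpr` (= 1 - Sp) and
#'   `tpr` (= Sn), starting at (0,0) and ending at (1,1).
#' @export
roc_points <- function(truth, score) {
  truth <- as.integer(truth)
  assert_two_classes(truth)
  n_pos <- sum(truth == 1); n_neg <- sum(truth == 0)
  ord <- order(score, decreasing = TRUE)
  truth <- truth[ord]; score <- score[ord]
  # one step per distinct threshold value
  last_of_group <- c(score[-1] != score[-length(score)], TRUE)
  tp <- cumsum(truth == 1)[last_of_group]
  fp <- cumsum(truth == 0)[last_of_group]
  out <- tibble::tibble(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  class(out) <- c("roc_points", class(out))
  out
}

#' @method autoplot roc_points
#' @export
autoplot.roc_points <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - Sp (false-positive rate)",
                  y = "Sn (true-positive rate)") +
    ggplot2::theme_minimal()
}

#' Full metrics report from predictions
#'
#' @param truth binary 0/1 vector.
#' @param estimate predicted 0/1 labels.
#' @param score optional positive-class scores; enables `AUC`.
#' @return One-row tibble `Sn`, `Sp`, `ACC`, `MCC`, `AUC` (`AUC` is `NA`
#'   without scores).
#' @export
classification_metrics <- function(truth, estimate, score = NULL) {
  out <- metrics_from_counts(confusion_counts(truth, estimate))
  out$AUC <- if (is.null(score)) NA_real_ else roc_auc(truth, score)
  out
}

#' Stratified k-fold cross-validation
#'
#' Splits the feature table into stratified folds, trains the given model
#' on each training partition, predicts the held-out fold, and computes one
#' canonical metrics report on the pooled out-of-fold predictions (per-fold
#' reports are also returned). Deterministic given `seed`.
#'
#' @param ft feature table (tibble, `label` last).
#' @param spec a [classifier_spec()] or [stack_spec()] describing the model
#'   to train in each fold.
#' @param folds number of folds (default 5).
#' @param seed integer seed controlling fold assignment and any stochastic
#'   training steps.
#' @return An object of class `cv_result`: list with `pooled` (one-row
#'   metrics tibble), `per_fold`, `predictions` (row, fold, truth, prob,
#'   estimate), `folds`, `seed`.
#' @export
cross_validate <- function(ft, spec, folds = 5, seed = 1) {
  assert_feature_table(ft)
  labels <- ft_labels(ft)
  assert_two_classes(labels)
  fold_id <- make_folds(labels, folds, seed)
  n <- nrow(ft)
  prob <- numeric(n); est <- integer(n)
  for (f in seq_len(folds)) {
    train <- ft[fold_id != f, , drop = FALSE]
    test <- ft[fold_id == f, , drop = FALSE]
    model <- train_spec(spec, train, seed = derive_seed(seed, f))
    pred <- predict(model, test)
    prob[fold_id == f] <- pred$.pred_prob
    est[fold_id == f] <- pred$.pred_class
  }
  predictions <- tibble::tibble(row = seq_len(n), fold = fold_id,
                                truth = labels, prob = prob, estimate = est)
  per_fold <- purrr::map_dfr(seq_len(folds), function(f) {
    p <- predictions[predictions$fold == f, ]
    dplyr::bind_cols(tibble::tibble(fold = f),
                     classification_metrics(p$truth, p$estimate, p$prob))
  })
  structure(list(pooled = classification_metrics(labels, est, prob),
                 per_fold = per_fold, predictions = predictions,
                 folds = folds, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold stratified cross-validation (seed %d), pooled metrics:\n",
              x$folds, x$seed))
  print(x$pooled)
  invisible(x)
}

#' @describeIn cross_validate per-fold metrics as a tibble.
#' @param x a `cv_result`.
#' @param ... unused.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$per_fold

#' @describeIn cross_validate pooled metrics as a one-row tibble.
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  dplyr::bind_cols(x$pooled, tibble::tibble(folds = x$folds, seed = x$seed))
}

#' Evaluate a trained model on an untouched test set
#'
#' The test feature table must live in the same feature space as the
#' training table (for PSTNPss this means encoding the test sequences with
#' the model fitted on the training set).
#'
#' @param model a trained model with a `predict` method returning
#'   `.pred_class` / `.pred_prob` (e.g. a [train_stacking()] fit).
#' @param test_ft labelled test feature table.
#' @return One-row metrics tibble `Sn`, `Sp`, `ACC`, `MCC`, `AUC`.
#' @export
independent_test <- function(model, test_ft) {
  assert_feature_table(test_ft)
  pred <- predict(model, test_ft)
  classification_metrics(ft_labels(test_ft), pred$.pred_class,
                         pred$.pred_prob)
}

#' Format a metrics report as percentages
#'
#' @param metrics one-row metrics tibble (fractions).
#' @param digits decimal places (default 2, matching conventional reporting).
#' @return Tibble with the same columns, values in percent.
#' @export
metrics_as_percent <- function(metrics, digits = 2) {
  dplyr::mutate(metrics, dplyr::across(
    dplyr::any_of(c("Sn", "Sp", "ACC", "MCC", "AUC")),
    ~ round(100 * .x, digits)))
}

# stable sub-seed per fold / stage, kept inside 32-bit range
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 131L + k * 7919) %% 2147483587)
}
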