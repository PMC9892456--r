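# Chi-square feature ranking, incremental feature selection (IFS) with
# cross-validated accuracy, and the greedy feature-scheme combination
# search. Because propensity features can be negative, every feature is
# min-max scaled to [0,1] before chi-square scoring; the score compares
# the per-class sums of the scaled feature with their expectation under
# the class proportions.

# min-max scale a matrix columnwise to [0,1]; constant columns -> all 0
minmax_scale <- function(X) {
  rng <- apply(X, 2L, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1
  sweep(sweep(X, 2L, rng[1, ], "-"), 2L, span, "/")
}

#' Rank features by chi-square score
#'
#' Each feature is min-max scaled to `[0, 1]`, then scored by the standard
#' feature-selection chi-square statistic: observed per-class sums of the
#' scaled feature against the expected sums under the class proportions,
#' `sum((obs - exp)^2 / exp)` over the two classes. Constant features score
#' 0. Ties in the ranking are broken by ascending original column index.
#'
#' @param ft labelled feature table with both classes and >= 2 samples.
#' @return A tibble of class `feature_ranking`, sorted by descending
#'   `score`: columns `rank`, `feature`, `index` (original column), `score`.
#' @export
chi2_scores <- function(ft) {
  assert_feature_table(ft)
  y <- ft_labels(ft)
  assert_two_classes(y)
  X <- minmax_scale(ft_matrix(ft))
  n <- nrow(X)
  prior <- table(factor(y, levels = c(0, 1))) / n
  obs <- rbind(colSums(X[y == 0, , drop = FALSE]),
               colSums(X[y == 1, , drop = FALSE]))
  total <- colSums(obs)
  expd <- outer(as.numeric(prior), total)
  chi <- colSums(ifelse(expd > 0, (obs - expd)^2 / expd, 0))
  out <- tibble::tibble(feature = colnames(X),
                        index = seq_along(chi),
                        score = as.numeric(chi))
  out <- dplyr::arrange(out, dplyr::desc(.data$score), .data$index)
  out <- dplyr::mutate(out, rank = dplyr::row_number(),
                       .before = "feature")
  class(out) <- c("feature_ranking", class(out))
  out
}

#' Top-ranked features
#'
#' @param ranking a [chi2_scores()] ranking.
#' @param top how many features to report (default 20).
#' @return The first `top` rows of the ranking (names + scores,
#'   descending).
#' @export
feature_importance_report <- function(ranking, top = 20) {
  stopifnot(top >= 1, top <= nrow(ranking))
  utils::head(ranking, top)
}

#' @method autoplot feature_ranking
#' @export
autoplot.feature_ranking <- function(object, top = 20, ...) {
  d <- feature_importance_report(object, min(top, nrow(object)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score,
                                  y = stats::reorder(.data$feature,
                                                     .data$score))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "chi-square score", y = NULL) +
    ggplot2::theme_minimal()
}

#' Incremental feature selection
#'
#' Walks prefixes of the chi-square ranking: for each prefix size
#' `1..n`, the classifier is cross-validated on the top-ranked
#' features and the pooled out-of-fold accuracy recorded. The selected
#' size `k_opt` is the smallest prefix attaining the maximum of the
#' accuracy curve. One fold assignment (from `seed`) is shared by every
#' prefix so curve points are comparable.
#'
#' @param ft labelled feature table.
#' @param ranking a [chi2_scores()] ranking covering the features of `ft`;
#'   computed on `ft` itself when `NULL`.
#' @param classifier [classifier_spec()] used to score prefixes (LR by
#'   default).
#' @param folds,seed cross-validation controls.
#' @param max_features optional cap on the number of prefixes searched.
#' @return An object of class `ifs_result`: list with `acc_curve` (tibble
#'   `n_features`, `acc`), `k_opt`, `selected` (feature names), `ranking`,
#'   `classifier`, `folds`, `seed`.
#' @export
incremental_feature_selection <- function(ft, ranking = NULL,
                                          classifier = classifier_spec("LR"),
                                          folds = 5, seed = 1,
                                          max_features = Inf) {
  assert_feature_table(ft)
  if (is.null(ranking)) ranking <- chi2_scores(ft)
  feats <- ft_feature_names(ft)
  if (!setequal(ranking$feature, feats)) {
    stop("ranking does not cover exactly the features of `ft`", call. = FALSE)
  }
  labels <- ft_labels(ft)
  fold_id <- make_folds(labels, folds, seed)
  n_try <- min(length(feats), max_features)
  acc <- purrr::map_dbl(seq_len(n_try), function(k) {
    sub <- ft[c(ranking$feature[seq_len(k)], "label")]
    prefix_cv_acc(sub, classifier, fold_id, seed)
  })
  k_opt <- which.max(acc)   # which.max returns the first (smallest) argmax
  structure(list(acc_curve = tibble::tibble(n_features = seq_len(n_try),
                                            acc = acc),
                 k_opt = k_opt,
                 selected = ranking$feature[seq_len(k_opt)],
                 ranking = ranking, classifier = classifier,
                 folds = folds, seed = seed),
            class = "ifs_result")
}

# pooled out-of-fold accuracy for one feature subset under a fixed fold
# assignment (shared across IFS prefixes)
prefix_cv_acc <- function(ft, classifier, fold_id, seed) {
  labels <- ft_labels(ft)
  est <- integer(nrow(ft))
  for (f in sort(unique(fold_id))) {
    model <- fit_classifier(classifier, ft[fold_id != f, , drop = FALSE],
                            seed = derive_seed(seed, f))
    est[fold_id == f] <- predict(model, ft[fold_id == f, , drop = FALSE])$.pred_class
  }
  mean(est == labels)
}

#' @export
print.ifs_result <- function(x, ...) {
  cat(sprintf("IFS over %d prefixes (%s, %d-fold CV, seed %d)\n",
              nrow(x$acc_curve), x$classifier$name, x$folds, x$seed))
  cat(sprintf("optimal subset: top %d features, pooled ACC %.4f\n",
              x$k_opt, x$acc_curve$acc[x$k_opt]))
  invisible(x)
}

#' @describeIn incremental_feature_selection the accuracy curve as a
#'   tibble.
#' @param x an `ifs_result`.
#' @param ... unused.
#' @method tidy ifs_result
#' @export
tidy.ifs_result <- function(x, ...) x$acc_curve

#' @describeIn incremental_feature_selection one-row summary (`k_opt`,
#'   best accuracy, controls).
#' @method glance ifs_result
#' @export
glance.ifs_result <- function(x, ...) {
  tibble::tibble(k_opt = x$k_opt, best_acc = x$acc_curve$acc[x$k_opt],
                 n_features = nrow(x$acc_curve),
                 classifier = x$classifier$name,
                 folds = x$folds, seed = x$seed)
}

#' @method autoplot ifs_result
#' @export
autoplot.ifs_result <- function(object, ...) {
  ggplot2::ggplot(object$acc_curve,
                  ggplot2::aes(x = .data$n_features, y = .data$acc)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$k_opt, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "number of top-ranked features",
                  y = "cross-validated ACC") +
    ggplot2::theme_minimal()
}

#' Restrict a feature table to an IFS-selected subset
#'
#' @param ft labelled feature table.
#' @param ifs an [incremental_feature_selection()] result.
#' @return `ft` with only the selected features (plus `label`).
#' @export
select_features <- function(ft, ifs) {
  stopifnot(inherits(ifs, "ifs_result"))
  ft[c(ifs$selected, "label")]
}

#' Greedy feature-scheme combination search
#'
#' Given per-scheme feature tables (typically each restricted to its
#' IFS-selected features), ranks the schemes by single-scheme
#' cross-validated accuracy, then evaluates the cumulative concatenations
#' (best scheme; best + second; ...; all schemes) with the same classifier
#' and folds. The combination with maximal accuracy is flagged, ties going
#' to the smaller combination.
#'
#' @param scheme_tables named list of labelled feature tables with
#'   identical row order and labels.
#' @param classifier [classifier_spec()] used throughout (LR by default).
#' @param folds,seed cross-validation controls.
#' @return Tibble with one row per cumulative combination: `combination`,
#'   `n_schemes`, `n_features`, metrics (`ACC`, `MCC`, `Sn`, `Sp`, `AUC`),
#'   logical `best`; single-scheme accuracies in attribute
#'   `scheme_order`.
#' @export
combine_schemes <- function(scheme_tables, classifier = classifier_spec("LR"),
                            folds = 5, seed = 1) {
  stopifnot(length(scheme_tables) >= 1, !is.null(names(scheme_tables)))
  labels <- ft_labels(scheme_tables[[1]])
  for (tab in scheme_tables) {
    if (!identical(ft_labels(tab), labels)) {
      stop("all scheme tables must carry identical labels in the same order",
           call. = FALSE)
    }
  }
  single_acc <- purrr::map_dbl(scheme_tables, function(tab) {
    cross_validate(tab, classifier, folds = folds, seed = seed)$pooled$ACC
  })
  ord <- order(-single_acc, seq_along(single_acc))
  scheme_tables <- scheme_tables[ord]
  rows <- purrr::map_dfr(seq_along(scheme_tables), function(k) {
    feats <- purrr::map(scheme_tables[seq_len(k)],
                        ~ .x[ft_feature_names(.x)])
    combined <- dplyr::bind_cols(feats, .name_repair = "minimal")
    combined$label <- labels
    cv <- cross_validate(assert_feature_table(combined), classifier,
                         folds = folds, seed = seed)
    dplyr::bind_cols(
      tibble::tibble(combination = paste(names(scheme_tables)[seq_len(k)],
                                         collapse = "+"),
                     n_schemes = k,
                     n_features = ncol(combined) - 1L),
      cv$pooled)
  })
  best <- order(-rows$ACC, rows$n_schemes)[[1]]
  rows$best <- seq_len(nrow(rows)) == best
  attr(rows, "scheme_order") <- tibble::tibble(
    scheme = names(single_acc)[ord], single_ACC = single_acc[ord])
  rows
}
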