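# Stacked generalization with out-of-fold meta-features. Base classifiers
# are trained inside a stratified k-fold loop; the positive-class
# probability each base assigns to the samples of its held-out fold forms
# the meta-feature matrix (n_samples x n_bases), so the meta-learner never
# sees a base output produced by a model that trained on that sample.
# After meta-training, each base is refit on the full training data for
# deployment.

#' Describe a stacking ensemble
#'
#' @param bases list of base [classifier_spec()]s (or character names, e.g.
#'   `c("RF", "LR")`).
#' @param meta meta-classifier spec; logistic regression by default.
#' @param folds folds for the out-of-fold meta-feature construction.
#' @return An object of class `stack_spec`, usable with [train_stacking()]
#'   and [cross_validate()].
#' @export
#' @examples
#' stack_spec(c("RF", "LR"))
stack_spec <- function(bases = c("RF", "LR"), meta = classifier_spec("LR"),
                       folds = 5) {
  if (is.character(bases)) bases <- lapply(bases, classifier_spec)
  stopifnot(length(bases) >= 1,
            all(vapply(bases, inherits, logical(1), "classifier_spec")),
            inherits(meta, "classifier_spec"), folds >= 2)
  structure(list(bases = bases, meta = meta, folds = folds),
            class = "stack_spec")
}

#' @export
print.stack_spec <- function(x, ...) {
  cat(sprintf("<stack_spec: bases %s; meta %s; %d meta-feature folds>\n",
              paste(vapply(x$bases, `[[`, character(1), "name"),
                    collapse = "+"),
              x$meta$name, x$folds))
  invisible(x)
}

meta_feature_names <- function(base_specs) {
  nm <- vapply(base_specs, `[[`, character(1), "name")
  paste0("base", seq_along(nm), "_", nm)
}

#' Train a stacking ensemble
#'
#' Step 1 builds the out-of-fold meta-feature matrix: within a stratified
#' k-fold split, each base classifier is trained on k-1 folds and its
#' positive-class probabilities on the held-out fold are recorded. Step 2
#' fits the meta-classifier on those out-of-fold probabilities against the
#' true labels. Finally each base classifier is refit on the full training
#' table for deployment.
#'
#' @param ft labelled feature table with at least `folds` samples per
#'   class.
#' @param spec a [stack_spec()]; alternatively pass `bases`/`meta` directly.
#' @param bases,meta,folds used when `spec` is `NULL`; see [stack_spec()].
#' @param seed integer seed (fold assignment + stochastic base learners).
#' @return An object of class `stack_model` with the fitted bases, the
#'   fitted meta-classifier, the meta-feature matrix and the fold
#'   assignment used to build it.
#' @export
train_stacking <- function(ft, spec = NULL, bases = c("RF", "LR"),
                           meta = classifier_spec("LR"), folds = 5,
                           seed = 1) {
  if (is.null(spec)) spec <- stack_spec(bases, meta, folds)
  stopifnot(inherits(spec, "stack_spec"))
  assert_feature_table(ft)
  labels <- ft_labels(ft)
  assert_two_classes(labels)
  n <- nrow(ft)
  n_base <- length(spec$bases)
  fold_id <- make_folds(labels, spec$folds, seed)
  meta_X <- matrix(NA_real_, nrow = n, ncol = n_base,
                   dimnames = list(NULL, meta_feature_names(spec$bases)))
  for (f in seq_len(spec$folds)) {
    train <- ft[fold_id != f, , drop = FALSE]
    hold <- ft[fold_id == f, , drop = FALSE]
    for (b in seq_len(n_base)) {
      base_fit <- fit_classifier(spec$bases[[b]], train,
                                 seed = derive_seed(seed, f * 100L + b))
      meta_X[fold_id == f, b] <- predict(base_fit, hold)$.pred_prob
    }
  }
  meta_ft <- tibble::as_tibble(meta_X)
  meta_ft$label <- labels
  meta_fit <- fit_classifier(spec$meta, meta_ft,
                             seed = derive_seed(seed, 999L))
  full_bases <- lapply(seq_len(n_base), function(b) {
    fit_classifier(spec$bases[[b]], ft, seed = derive_seed(seed, b))
  })
  structure(list(spec = spec, base_fits = full_bases, meta_fit = meta_fit,
                 meta_features = meta_ft, fold_id = fold_id, seed = seed,
                 features = ft_feature_names(ft)),
            class = "stack_model")
}

#' @export
train_spec.stack_spec <- function(spec, ft, seed = 1) {
  train_stacking(ft, spec = spec, seed = seed)
}

#' @export
print.stack_model <- function(x, ...) {
  print(x$spec)
  cat(sprintf("trained on %d samples x %d features (seed %d)\n",
              nrow(x$meta_features), length(x$features), x$seed))
  invisible(x)
}

#' Predict with a trained stacking ensemble
#'
#' Full-data base fits produce one positive-class probability per base;
#' the meta-classifier maps that vector to the final probability. Labels
#' use a 0.5 threshold.
#'
#' @param object a [train_stacking()] fit.
#' @param newdata feature table (label column optional) or numeric matrix
#'   in the training feature space.
#' @param ... unused.
#' @return Tibble with `.pred_class` (0/1) and `.pred_prob`.
#' @export
predict.stack_model <- function(object, newdata, ...) {
  base_probs <- vapply(object$base_fits,
                       function(b) predict(b, newdata)$.pred_prob,
                       numeric(if (is.data.frame(newdata)) nrow(newdata)
                               else nrow(as.matrix(newdata))))
  if (is.null(dim(base_probs))) base_probs <- matrix(base_probs, nrow = 1)
  colnames(base_probs) <- meta_feature_names(object$spec$bases)
  predict(object$meta_fit, base_probs)
}

#' @describeIn train_stacking base-classifier composition as a tibble.
#' @param x a `stack_model`.
#' @param ... unused.
#' @method tidy stack_model
#' @export
tidy.stack_model <- function(x, ...) {
  tibble::tibble(
    role = c(rep("base", length(x$spec$bases)), "meta"),
    classifier = c(vapply(x$spec$bases, `[[`, character(1), "name"),
                   x$spec$meta$name))
}

#' @describeIn train_stacking one-row training summary.
#' @method glance stack_model
#' @export
glance.stack_model <- function(x, ...) {
  tibble::tibble(n_bases = length(x$spec$bases),
                 meta = x$spec$meta$name,
                 folds = x$spec$folds,
                 n_train = nrow(x$meta_features),
                 n_features = length(x$features),
                 seed = x$seed)
}

#' Save / load a trained stacking model
#'
#' Persists the whole fitted object (base fits, meta fit, feature names,
#' seed) so reloaded models reproduce identical predictions.
#'
#' @param model a `stack_model`.
#' @param path file path (`.rds`).
#' @return `path` invisibly / the restored model.
#' @export
write_stack_model <- function(model, path) {
  stopifnot(inherits(model, "stack_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_stack_model
#' @export
read_stack_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "stack_model"))
  model
}

#' Compare base-classifier combinations for the stacked model
#'
#' Cross-validates one stacked model per base-classifier combination (all
#' with the same meta-classifier, folds and seed) and, when a test table is
#' given, also evaluates each combination on the independent test set after
#' training on the full table. The best combination is flagged by CV
#' accuracy, ties broken by independent-test accuracy, then by fewest
#' bases.
#'
#' @param ft labelled training feature table.
#' @param combos list of base combinations, each a character vector or list
#'   of specs, e.g. `list(c("RF","LR"), c("RF","LR","SVM"))`.
#' @param meta meta-classifier spec (LR by default).
#' @param folds,seed cross-validation controls.
#' @param test_ft optional independent test table in the same feature
#'   space.
#' @return Tibble with one row per combination: `combination`, `n_bases`,
#'   CV metrics (`ACC`, `MCC`, `Sn`, `Sp`, `AUC`), test metrics
#'   (`test_ACC`, ... when `test_ft` given) and logical `best`.
#' @export
evaluate_base_combinations <- function(ft, combos, meta = classifier_spec("LR"),
                                       folds = 5, seed = 1, test_ft = NULL) {
  stopifnot(length(combos) >= 1)
  rows <- purrr::map_dfr(combos, function(combo) {
    spec <- stack_spec(combo, meta = meta, folds = folds)
    label <- paste(vapply(spec$bases, `[[`, character(1), "name"),
                   collapse = "+")
    cv <- cross_validate(ft, spec, folds = folds, seed = seed)
    row <- dplyr::bind_cols(
      tibble::tibble(combination = label, n_bases = length(spec$bases)),
      cv$pooled)
    if (!is.null(test_ft)) {
      model <- train_stacking(ft, spec = spec, seed = seed)
      test <- independent_test(model, test_ft)
      names(test) <- paste0("test_", names(test))
      row <- dplyr::bind_cols(row, test)
    }
    row
  })
  ord <- order(-rows$ACC,
               if ("test_ACC" %in% names(rows)) -rows$test_ACC else rows$n_bases,
               rows$n_bases)
  rows$best <- seq_len(nrow(rows)) == ord[[1]]
  rows
}
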