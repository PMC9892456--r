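# The four candidate base learners: random forest (RF), logistic
# regression (LR), support vector machine (SVM, radial kernel) and
# Gaussian naive Bayes (GaNB), each behind one fit/predict surface so the
# stacking and cross-validation code never touches the backends directly.

CLASSIFIER_NAMES <- c("RF", "LR", "SVM", "GaNB")

classifier_defaults <- function(name) {
  switch(name,
         RF = list(ntree = 100),
         LR = list(alpha = 0, lambda = NULL),   # NULL -> 1/n at fit time
         SVM = list(kernel = "radial", cost = 1.0, gamma = NULL),
         GaNB = list(var_floor = 1e-6))
}

#' Describe a base or meta classifier
#'
#' Builds a specification for one of the four supported algorithms with its
#' default parameters: `RF` (random forest, 100 trees), `LR`
#' (ridge-penalised logistic regression, penalty `lambda = 1/n` mirroring
#' the common C = 1.0 default), `SVM` (radial kernel, cost 1.0, probability
#' outputs) and `GaNB` (Gaussian naive Bayes with a small variance floor
#' for numerically constant features). Parameters passed via `...` override
#' the defaults.
#'
#' @param name one of `"RF"`, `"LR"`, `"SVM"`, `"GaNB"`.
#' @param ... parameter overrides (e.g. `ntree = 500`, `cost = 2`).
#' @return An object of class `classifier_spec`.
#' @export
#' @examples
#' classifier_spec("RF")
#' classifier_spec("SVM", cost = 2)
classifier_spec <- function(name, ...) {
  if (length(name) != 1 || !name %in% CLASSIFIER_NAMES) {
    stop("unknown classifier '", paste(name, collapse = ","),
         "'; supported: ", paste(CLASSIFIER_NAMES, collapse = ", "),
         call. = FALSE)
  }
  params <- utils::modifyList(classifier_defaults(name), list(...))
  bad <- setdiff(names(params), names(classifier_defaults(name)))
  if (length(bad)) {
    stop("unknown parameter(s) for ", name, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(name = name, params = params), class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  ps <- vapply(x$params, function(p) if (is.null(p)) "default" else
    format(p), character(1))
  cat(sprintf("<classifier_spec %s: %s>\n", x$name,
              paste(names(ps), ps, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Fit a classifier to a labelled feature table
#'
#' @param spec a [classifier_spec()].
#' @param ft feature table (tibble, `label` last) with both classes.
#' @param seed integer seed for the stochastic backends (RF bootstrap, SVM
#'   probability calibration).
#' @return An object of class `psistack_classifier` supporting
#'   `predict(object, ft)`.
#' @export
fit_classifier <- function(spec, ft, seed = 1) {
  stopifnot(inherits(spec, "classifier_spec"))
  assert_feature_table(ft)
  X <- ft_matrix(ft)
  y <- ft_labels(ft)
  assert_two_classes(y)
  yf <- factor(y, levels = c(0, 1))
  p <- spec$params
  set.seed(seed)
  fit <- switch(
    spec$name,
    RF = randomForest::randomForest(x = X, y = yf, ntree = p$ntree),
    LR = fit_lr(X, y, alpha = p$alpha, lambda = p$lambda),
    SVM = e1071::svm(x = X, y = yf, kernel = p$kernel, cost = p$cost,
                     gamma = if (is.null(p$gamma)) 1 / ncol(X) else p$gamma,
                     probability = TRUE, scale = FALSE),
    GaNB = fit_ganb(X, yf, var_floor = p$var_floor))
  structure(list(spec = spec, fit = fit, features = ft_feature_names(ft)),
            class = "psistack_classifier")
}

# ridge logistic regression; glmnet needs >= 2 columns, fall back to glm
# for a single-feature design
fit_lr <- function(X, y, alpha = 0, lambda = NULL) {
  if (is.null(lambda)) lambda <- 1 / nrow(X)
  if (ncol(X) >= 2) {
    fit <- glmnet::glmnet(X, y, family = "binomial", alpha = alpha,
                          lambda = lambda, standardize = FALSE)
    structure(list(engine = "glmnet", fit = fit, lambda = lambda),
              class = "psistack_lr")
  } else {
    df <- data.frame(y = y, x = X[, 1])
    fit <- suppressWarnings(stats::glm(y ~ x, data = df, family = stats::binomial()))
    structure(list(engine = "glm", fit = fit), class = "psistack_lr")
  }
}

predict_lr_prob <- function(object, X) {
  if (object$engine == "glmnet") {
    as.numeric(stats::predict(object$fit, newx = X, type = "response",
                              s = object$lambda))
  } else {
    as.numeric(stats::predict(object$fit, newdata = data.frame(x = X[, 1]),
                              type = "response"))
  }
}

# Gaussian naive Bayes with a variance floor so one-hot features that are
# constant within a class do not produce degenerate densities
fit_ganb <- function(X, yf, var_floor = 1e-6) {
  fit <- e1071::naiveBayes(x = as.data.frame(X), y = yf)
  fit$tables <- lapply(fit$tables, function(tab) {
    tab[, 2] <- pmax(tab[, 2], sqrt(var_floor))
    tab
  })
  fit
}

#' @export
predict.psistack_classifier <- function(object, newdata, ...) {
  X <- if (is.data.frame(newdata)) {
    miss <- setdiff(object$features, names(newdata))
    if (length(miss)) {
      stop("newdata is missing ", length(miss), " training feature(s), e.g. ",
           miss[[1]], call. = FALSE)
    }
    ft_matrix(newdata, object$features)
  } else {
    if (ncol(newdata) != length(object$features)) {
      stop("newdata has ", ncol(newdata), " columns; model expects ",
           length(object$features), call. = FALSE)
    }
    newdata
  }
  prob <- switch(
    object$spec$name,
    RF = stats::predict(object$fit, X, type = "prob")[, "1"],
    LR = predict_lr_prob(object$fit, X),
    SVM = attr(stats::predict(object$fit, X, probability = TRUE),
               "probabilities")[, "1"],
    GaNB = stats::predict(object$fit, as.data.frame(X), type = "raw")[, "1"])
  prob <- pmin(pmax(as.numeric(prob), 0), 1)
  tibble::tibble(.pred_class = as.integer(prob >= 0.5), .pred_prob = prob)
}

# unified trainer used by cross_validate(): dispatch on the spec type
train_spec <- function(spec, ft, seed = 1) UseMethod("train_spec")

#' @export
train_spec.classifier_spec <- function(spec, ft, seed = 1) {
  fit_classifier(spec, ft, seed = seed)
}

#' Hyperparameter grids quoted for the candidate algorithms
#'
#' Candidate grids for optional tuning: RF trees 100..1000 by 100, SVM cost
#' 1..15 by 1 and gamma `2^(-10..5)`. Defaults are used everywhere in the
#' reference pipeline; this utility exists for exploratory tuning only.
#'
#' @param name classifier name.
#' @return A tibble with one row per candidate parameter setting.
#' @export
classifier_grid <- function(name) {
  switch(name,
         RF = tibble::tibble(ntree = seq(100, 1000, by = 100)),
         SVM = tidyr::expand_grid(cost = seq(1, 15, by = 1),
                                  gamma = 2^seq(-10, 5, by = 1)),
         LR = tibble::tibble(lambda = 10^seq(-4, 1, by = 1)),
         GaNB = tibble::tibble(var_floor = 10^seq(-9, -3, by = 2)),
         stop("unknown classifier '", name, "'", call. = FALSE))
}

#' Grid-search a classifier by cross-validated accuracy
#'
#' @param ft feature table.
#' @param name classifier name.
#' @param grid tibble of parameter settings (default [classifier_grid()]).
#' @param folds,seed cross-validation controls.
#' @return The grid with an `ACC` column, sorted by decreasing `ACC`.
#' @export
grid_search <- function(ft, name, grid = classifier_grid(name),
                        folds = 5, seed = 1) {
  acc <- purrr::map_dbl(seq_len(nrow(grid)), function(i) {
    spec <- do.call(classifier_spec, c(list(name = name), as.list(grid[i, ])))
    cross_validate(ft, spec, folds = folds, seed = seed)$pooled$ACC
  })
  dplyr::arrange(dplyr::mutate(grid, ACC = acc), dplyr::desc(.data$ACC))
}
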