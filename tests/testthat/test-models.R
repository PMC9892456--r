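test_that("classifier specs carry the documented defaults and reject unknowns", {
  expect_equal(classifier_spec("RF")$params$ntree, 100)
  svm <- classifier_spec("SVM")
  expect_equal(svm$params$kernel, "radial")
  expect_equal(svm$params$cost, 1.0)
  expect_error(classifier_spec("XGB"), "unknown classifier")
  expect_error(classifier_spec("RF", trees = 5), "unknown parameter")
  expect_equal(classifier_spec("RF", ntree = 250)$params$ntree, 250)
})

test_that("all four classifiers fit, predict probabilities and separate easy data", {
  ds <- simulate_psi_dataset(n_pos = 30, n_neg = 30, delta = 1, seed = 1)
  ft <- encode_sequences(ds, "PSTNPss", fit_pstnpss_on_data = TRUE)
  for (name in c("RF", "LR", "SVM", "GaNB")) {
    fit <- fit_classifier(classifier_spec(name), ft, seed = 2)
    pred <- predict(fit, ft)
    expect_true(all(pred$.pred_prob >= 0 & pred$.pred_prob <= 1), info = name)
    expect_true(all(pred$.pred_class %in% 0:1), info = name)
    expect_gte(mean(pred$.pred_class == ft$label), 0.95)
  }
})

test_that("hyperparameter grids expose the quoted ranges", {
  expect_equal(classifier_grid("RF")$ntree, seq(100, 1000, by = 100))
  g <- classifier_grid("SVM")
  expect_setequal(unique(g$cost), 1:15)
  expect_equal(sort(unique(g$gamma)), 2^(-10:5))
})

test_that("stacking builds an n x n_bases out-of-fold meta-feature matrix", {
  ds <- simulate_psi_dataset(n_pos = 50, n_neg = 50, delta = 0.6, seed = 3)
  ft <- encode_sequences(ds, "PSTNPss", fit_pstnpss_on_data = TRUE)
  model <- train_stacking(ft, bases = c("RF", "LR"), folds = 5, seed = 4)
  expect_equal(dim(model$meta_features), c(100, 3))  # 2 bases + label
  expect_named(model$meta_features, c("base1_RF", "base2_LR", "label"))
  expect_equal(length(model$base_fits), 2)
  expect_equal(model$spec$meta$name, "LR")
})

test_that("meta-features come from fold-held-out base models (oracle loop)", {
  ds <- simulate_psi_dataset(n_pos = 30, n_neg = 30, delta = 0.5, seed = 5)
  ft <- encode_sequences(ds, "PSTNPss", fit_pstnpss_on_data = TRUE)
  folds <- 3; seed <- 7
  model <- train_stacking(ft, bases = c("RF", "LR"), folds = folds,
                          seed = seed)
  # independently coded fold loop with the same fold assignment and seeds
  fold_id <- make_folds(ft$label, folds, seed)
  expect_identical(fold_id, model$fold_id)
  specs <- list(classifier_spec("RF"), classifier_spec("LR"))
  for (f in seq_len(folds)) {
    for (b in 1:2) {
      fit <- fit_classifier(specs[[b]], ft[fold_id != f, ],
                            seed = psistack:::derive_seed(seed, f * 100L + b))
      expect_equal(
        unname(as.matrix(model$meta_features)[fold_id == f, b]),
        predict(fit, ft[fold_id == f, ])$.pred_prob,
        tolerance = 1e-12)
    }
  }
})

test_that("stacked predictions are per-sample and reproduce training labels on separable data", {
  ds <- simulate_psi_dataset(n_pos = 20, n_neg = 20, delta = 1, seed = 6)
  ft <- encode_sequences(ds, "PSTNPss", fit_pstnpss_on_data = TRUE)
  model <- train_stacking(ft, bases = c("RF", "LR"), folds = 4, seed = 1)
  pred <- predict(model, ft)
  expect_equal(pred$.pred_class, ft$label)
  # single sample and row duplication
  one <- predict(model, ft[3, ])
  expect_equal(nrow(one), 1)
  dup <- predict(model, ft[c(3, 3, 5), ])
  expect_equal(dup$.pred_prob[[1]], dup$.pred_prob[[2]])
  expect_equal(dup$.pred_prob[[1]], one$.pred_prob[[1]])
  expect_error(predict(model, ft[, 1:5]), "missing")
})

test_that("stacking a single LR base under an LR meta is near the plain model", {
  ds <- simulate_psi_dataset(n_pos = 60, n_neg = 60, delta = 0.6, seed = 8)
  ft <- encode_sequences(ds, "PSTNPss", fit_pstnpss_on_data = TRUE)
  test_ds <- simulate_psi_dataset(n_pos = 60, n_neg = 60, delta = 0.6,
                                  seed = 9)
  test_ft <- encode_sequences(test_ds, "PSTNPss",
                              pstnpss_model = attr(ft, "pstnpss_model"))
  stacked <- train_stacking(ft, bases = "LR", folds = 5, seed = 2)
  plain <- fit_classifier(classifier_spec("LR"), ft, seed = 2)
  auc_stack <- roc_auc(test_ft$label, predict(stacked, test_ft)$.pred_prob)
  auc_plain <- roc_auc(test_ft$label, predict(plain, test_ft)$.pred_prob)
  expect_lt(abs(auc_stack - auc_plain), 0.05)
})

test_that("saved models reload and predict identically", {
  ds <- simulate_psi_dataset(n_pos = 20, n_neg = 20, delta = 0.8, seed = 10)
  ft <- encode_sequences(ds, "PSTNPss", fit_pstnpss_on_data = TRUE)
  model <- train_stacking(ft, bases = c("RF", "LR"), folds = 4, seed = 3)
  f <- withr::local_tempfile(fileext = ".rds")
  write_stack_model(model, f)
  back <- read_stack_model(f)
  expect_equal(predict(back, ft), predict(model, ft))
})

test_that("base-combination comparison reports CV (and test) metrics per combo", {
  ds <- simulate_psi_dataset(n_pos = 40, n_neg = 40, delta = 0.9, seed = 11)
  ft <- encode_sequences(ds, "PSTNPss", fit_pstnpss_on_data = TRUE)
  test_ds <- simulate_psi_dataset(n_pos = 20, n_neg = 20, delta = 0.9,
                                  seed = 12)
  test_ft <- encode_sequences(test_ds, "PSTNPss",
                              pstnpss_model = attr(ft, "pstnpss_model"))
  rep <- evaluate_base_combinations(
    ft, combos = list(c("RF", "LR"), c("RF", "LR", "GaNB")),
    folds = 3, seed = 1, test_ft = test_ft)
  expect_equal(rep$combination, c("RF+LR", "RF+LR+GaNB"))
  expect_true(all(c("ACC", "MCC", "Sn", "Sp", "AUC", "test_ACC") %in%
                    names(rep)))
  expect_equal(sum(rep$best), 1L)
  # determinism under a fixed seed
  rep2 <- evaluate_base_combinations(
    ft, combos = list(c("RF", "LR"), c("RF", "LR", "GaNB")),
    folds = 3, seed = 1, test_ft = test_ft)
  expect_equal(rep, rep2)
})

test_that("stacking rejects degenerate inputs", {
  ds <- simulate_psi_dataset(n_pos = 20, n_neg = 20, seed = 13)
  ft <- encode_sequences(ds, "binary")
  oneclass <- dplyr::mutate(ft, label = 1L)
  expect_error(train_stacking(oneclass, bases = "LR", folds = 3), "both classes")
  expect_error(stack_spec("RF", folds = 1))
  expect_error(stack_spec(character(0)))
})
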