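test_that("chi-square scores match the brute-force contingency oracle", {
  # frozen hand-derived case: balanced perfect association scores 2
  ft <- tibble::tibble(f1 = c(1, 1, 0, 0), label = c(1L, 1L, 0L, 0L))
  expect_equal(chi2_scores(ft)$score, 2)

  for (seed in 1:5) {
    ft <- rand_feature_table(n = 25, p = 20, seed = seed)
    ranking <- chi2_scores(ft)
    oracle <- oracle_chi2(ft)
    expect_equal(ranking$score[order(ranking$index)], unname(oracle),
                 tolerance = 1e-12)
    expect_true(all(diff(ranking$score) <= 1e-12))   # sorted non-increasing
    expect_true(all(ranking$score >= 0))
  }
})

test_that("constant and duplicated features behave as expected", {
  ft <- rand_feature_table(n = 20, p = 3, seed = 3)
  ft$const <- 5
  ft$dup <- ft$f1
  ft <- ft[c("f1", "f2", "f3", "const", "dup", "label")]
  ranking <- chi2_scores(ft)
  expect_equal(ranking$score[ranking$feature == "const"], 0)
  expect_equal(ranking$score[ranking$feature == "dup"],
               ranking$score[ranking$feature == "f1"])
  expect_error(chi2_scores(dplyr::mutate(ft, label = 1L)), "both classes")
})

test_that("chi-square ranking is invariant to sample order and affine rescaling", {
  ft <- rand_feature_table(n = 30, p = 6, seed = 4)
  base <- chi2_scores(ft)$score
  set.seed(1)
  shuffled <- ft[sample(nrow(ft)), ]
  expect_equal(chi2_scores(shuffled)$score, base, tolerance = 1e-12)
  rescaled <- dplyr::mutate(ft, f1 = 7 * f1 - 3, f2 = -2 * f2 + 10)
  r2 <- chi2_scores(rescaled)
  expect_equal(r2$score[r2$feature == "f1"], base[chi2_scores(ft)$feature == "f1"][1],
               tolerance = 1e-12)
})

test_that("IFS selects the smallest prefix attaining maximal accuracy", {
  # single feature: curve of length 1
  ft1 <- rand_feature_table(n = 20, p = 1, seed = 5)
  res1 <- incremental_feature_selection(ft1, folds = 2, seed = 1)
  expect_equal(nrow(res1$acc_curve), 1)
  expect_equal(res1$k_opt, 1L)

  # three informative features ranked on top, the rest pure noise
  set.seed(6)
  n <- 120
  y <- rep(c(0L, 1L), each = n / 2)
  signal <- sapply(1:3, function(i) y + rnorm(n, sd = 0.3))
  noise <- matrix(rnorm(n * 9), n)
  ft <- tibble::as_tibble(cbind(signal, noise), .name_repair = "minimal")
  names(ft) <- paste0("f", 1:12)
  ft$label <- y
  ranking <- chi2_scores(ft)
  expect_true(all(paste0("f", 1:3) %in% ranking$feature[1:3]))
  res <- incremental_feature_selection(ft, ranking, folds = 5, seed = 2)
  expect_equal(nrow(res$acc_curve), 12)
  expect_lte(res$k_opt, 6)
  expect_identical(res$selected, ranking$feature[seq_len(res$k_opt)])
  # k_opt is the smallest argmax of the curve
  expect_equal(res$k_opt, which.max(res$acc_curve$acc))
  expect_true(all(res$acc_curve$acc[res$k_opt] >= res$acc_curve$acc))
})

test_that("IFS prefix accuracies equal an independent fold-loop oracle", {
  ft <- rand_feature_table(n = 40, p = 4, seed = 7)
  folds <- 4; seed <- 3
  ranking <- chi2_scores(ft)
  res <- incremental_feature_selection(ft, ranking, folds = folds, seed = seed)
  fold_id <- make_folds(ft$label, folds, seed)
  for (k in seq_len(4)) {
    sub <- ft[c(ranking$feature[seq_len(k)], "label")]
    est <- integer(nrow(sub))
    for (f in 1:folds) {
      fit <- fit_classifier(classifier_spec("LR"), sub[fold_id != f, ],
                            seed = psistack:::derive_seed(seed, f))
      est[fold_id == f] <- predict(fit, sub[fold_id == f, ])$.pred_class
    }
    expect_equal(res$acc_curve$acc[[k]], mean(est == sub$label))
  }
})

test_that("IFS runs are reproducible and respect the feature cap", {
  ft <- rand_feature_table(n = 30, p = 6, seed = 8)
  a <- incremental_feature_selection(ft, folds = 3, seed = 5)
  b <- incremental_feature_selection(ft, folds = 3, seed = 5)
  expect_identical(a$acc_curve, b$acc_curve)
  capped <- incremental_feature_selection(ft, folds = 3, seed = 5,
                                          max_features = 4)
  expect_equal(nrow(capped$acc_curve), 4)
  expect_identical(capped$acc_curve$acc, a$acc_curve$acc[1:4])
})

test_that("importance report returns top-N names with descending scores", {
  ft <- rand_feature_table(n = 30, p = 8, seed = 9)
  ranking <- chi2_scores(ft)
  top1 <- feature_importance_report(ranking, top = 1)
  expect_equal(top1$feature, ranking$feature[[1]])
  expect_equal(nrow(feature_importance_report(ranking, top = 8)), 8)
  expect_error(feature_importance_report(ranking, top = 9))
})

test_that("scheme combination search orders schemes and flags the best concatenation", {
  ds <- simulate_psi_dataset(n_pos = 40, n_neg = 40, delta = 0.9, seed = 10)
  tabs <- list(
    PSTNPss = encode_sequences(ds, "PSTNPss", fit_pstnpss_on_data = TRUE),
    NCP = encode_sequences(ds, "NCP"))
  rep <- combine_schemes(tabs, folds = 3, seed = 1)
  expect_equal(nrow(rep), 2)
  expect_equal(rep$n_schemes, 1:2)
  expect_equal(sum(rep$best), 1L)
  ord <- attr(rep, "scheme_order")
  expect_true(all(diff(ord$single_ACC) <= 0))
  # combining the informative scheme with another cannot collapse accuracy
  expect_gte(max(rep$ACC), max(ord$single_ACC) - 0.02)
  expect_error(combine_schemes(list()), "length")
})
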