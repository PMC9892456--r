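# End-to-end pipeline: simulate/load -> validate -> encode -> (rank + IFS)
# -> stacked training -> cross-validation -> optional independent test,
# with every stage's seed recorded so a rerun from the same config
# reproduces identical outputs. The Rscript front-end in
# inst/scripts/psistack.R wraps these functions for shell use.

#' Cross-validate with fold-internal PSTNPss refitting
#'
#' Like [cross_validate()] but operating on raw sequences: within each
#' fold the propensity matrix is refit on the training partition only and
#' both partitions are encoded with it, so no label information from the
#' held-out fold ever reaches the encoder. The default pipeline instead
#' fits the propensity matrix once on the whole training set
#' ("whole-training" mode); this function provides the strict
#' ("fold-refit") alternative.
#'
#' @param data labelled sequence tibble (`id`, `sequence`, `label`).
#' @param spec [classifier_spec()] or [stack_spec()].
#' @param schemes encoding schemes, as in [encode_sequences()].
#' @param folds,seed cross-validation controls.
#' @param enac_window ENAC window width.
#' @return A `cv_result` (see [cross_validate()]) with attribute
#'   `pstnpss_mode = "fold-refit"`.
#' @export
cross_validate_sequences <- function(data, spec,
                                     schemes = c("PSTNPss", "PS3"),
                                     folds = 5, seed = 1, enac_window = 2) {
  labels <- as.integer(data$label)
  assert_two_classes(labels)
  fold_id <- make_folds(labels, folds, seed)
  n <- nrow(data)
  prob <- numeric(n); est <- integer(n)
  for (f in seq_len(folds)) {
    train <- data[fold_id != f, , drop = FALSE]
    test <- data[fold_id == f, , drop = FALSE]
    pmod <- if ("PSTNPss" %in% schemes) fit_pstnpss(train) else NULL
    train_ft <- encode_sequences(train, schemes, pstnpss_model = pmod,
                                 fit_pstnpss_on_data = is.null(pmod),
                                 enac_window = enac_window)
    test_ft <- encode_sequences(test, schemes, pstnpss_model = pmod,
                                enac_window = enac_window)
    model <- train_spec(spec, train_ft, seed = derive_seed(seed, f))
    pred <- predict(model, test_ft)
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
  out <- structure(list(pooled = classification_metrics(labels, est, prob),
                        per_fold = per_fold, predictions = predictions,
                        folds = folds, seed = seed),
                   class = "cv_result")
  attr(out, "pstnpss_mode") <- "fold-refit"
  out
}

default_run_config <- function() {
  list(
    simulate = list(n_pos = 200, n_neg = 200, L = 21, delta = 0.5, seed = 1),
    input = NULL,                       # list(pos =, neg =) FASTA paths
    test = NULL,                        # list(pos =, neg =) FASTA paths
    schemes = c("PSTNPss", "PS3"),
    enac_window = 2,
    pstnpss_mode = "fold-refit",        # or "whole-training"
    selection = list(enabled = FALSE, classifier = "LR", folds = 5,
                     seed = 1, max_features = Inf),
    stacking = list(bases = c("RF", "LR"), meta = "LR", folds = 5, seed = 1),
    outdir = NULL
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the full prediction pipeline from a single configuration
#'
#' Executes, in order: data acquisition (simulation or FASTA input),
#' validation, encoding (PSTNPss fitted on the training data), optional
#' chi-square ranking + incremental feature selection, stacked-model
#' cross-validation, full-data stacked training, and optional independent
#' testing. When `outdir` is set, all intermediate artifacts are written
#' there (feature table, ranking, IFS curve, model, metrics JSON, run
#' log); a rerun from the same config writes byte-identical metrics.
#'
#' @param config a named list overriding the defaults (see Details), or a
#'   path to a YAML file holding one.
#' @return Invisibly, a list: `data`, `feature_table`, `ranking`, `ifs`,
#'   `cv` (a `cv_result`), `model` (a `stack_model`), `test_metrics`
#'   (or `NULL`), `metrics` (list of percentage reports), `config`.
#' @details Config sections: `simulate` (n_pos, n_neg, L, delta, seed) or
#'   `input` (pos/neg FASTA paths); `test` (pos/neg FASTA paths);
#'   `schemes`; `enac_window`; `pstnpss_mode` ("fold-refit", the
#'   leakage-safe default in which the propensity matrix is refit inside
#'   every CV fold, or "whole-training", which fits it once on the full
#'   training set before CV; feature selection forces "whole-training");
#'   `selection` (enabled, classifier, folds, seed,
#'   max_features); `stacking` (bases, meta, folds, seed); `outdir`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_run_config(), config)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  data <- stage("data", {
    if (!is.null(cfg$input)) {
      read_fasta_pair(cfg$input$pos, cfg$input$neg)
    } else {
      do.call(simulate_psi_dataset, cfg$simulate)
    }
  })
  stage("validate", {
    report <- validate_sequence_set(data)
    if (!validation_passed(report)) {
      stop("dataset failed validation: ", nrow(report), " violation(s), ",
           "first: ", report$id[[1]], " (", report$problem[[1]], ")")
    }
  })

  schemes <- cfg$schemes
  ft <- stage("encode", {
    encode_sequences(data, schemes, fit_pstnpss_on_data = TRUE,
                     enac_window = cfg$enac_window)
  })
  pmod <- attr(ft, "pstnpss_model")

  ranking <- NULL; ifs <- NULL
  if (isTRUE(cfg$selection$enabled)) {
    ranking <- stage("rank", chi2_scores(ft))
    ifs <- stage("ifs", incremental_feature_selection(
      ft, ranking, classifier = classifier_spec(cfg$selection$classifier),
      folds = cfg$selection$folds, seed = cfg$selection$seed,
      max_features = cfg$selection$max_features))
    ft <- select_features(ft, ifs)
  }

  sspec <- stack_spec(cfg$stacking$bases,
                      meta = classifier_spec(cfg$stacking$meta),
                      folds = cfg$stacking$folds)
  # feature selection operates on the whole-training feature table, so its
  # CV necessarily uses the whole-training propensity fit
  if (isTRUE(cfg$selection$enabled)) cfg$pstnpss_mode <- "whole-training"
  if (!"PSTNPss" %in% schemes) cfg$pstnpss_mode <- "none"
  cv <- stage("cv", {
    if (identical(cfg$pstnpss_mode, "fold-refit") && "PSTNPss" %in% schemes) {
      cross_validate_sequences(data, sspec, schemes = schemes,
                               folds = cfg$stacking$folds,
                               seed = cfg$stacking$seed,
                               enac_window = cfg$enac_window)
    } else {
      cross_validate(ft, sspec, folds = cfg$stacking$folds,
                     seed = cfg$stacking$seed)
    }
  })
  model <- stage("train", train_stacking(ft, spec = sspec,
                                         seed = cfg$stacking$seed))

  test_metrics <- NULL
  if (!is.null(cfg$test)) {
    test_metrics <- stage("test", {
      test_data <- read_fasta_pair(cfg$test$pos, cfg$test$neg)
      test_ft <- encode_sequences(test_data, schemes, pstnpss_model = pmod,
                                  enac_window = cfg$enac_window)
      if (isTRUE(cfg$selection$enabled)) test_ft <- select_features(test_ft, ifs)
      independent_test(model, test_ft)
    })
  }

  metrics <- list(
    cv_pooled = as.list(metrics_as_percent(cv$pooled)),
    pstnpss_mode = cfg$pstnpss_mode,
    n_train = nrow(ft), n_features = length(ft_feature_names(ft)))
  if (!is.null(test_metrics)) {
    metrics$independent_test <- as.list(metrics_as_percent(test_metrics))
  }

  if (!is.null(cfg$outdir)) {
    stage("write", {
      dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
      out <- function(f) file.path(cfg$outdir, f)
      write_feature_table(ft, out("features.csv"))
      if (!is.null(pmod)) write_pstnpss(pmod, out("pstnpss_model.json"))
      if (!is.null(ranking)) readr::write_csv(ranking, out("ranking.csv"))
      if (!is.null(ifs)) readr::write_csv(ifs$acc_curve, out("ifs_curve.csv"))
      write_stack_model(model, out("model.rds"))
      jsonlite::write_json(metrics, out("metrics.json"), auto_unbox = TRUE,
                           digits = NA)
      log <- list(package_version = as.character(utils::packageVersion("psistack")),
                  config = cfg, config_hash = rlang::hash(cfg),
                  seeds = list(simulate = cfg$simulate$seed,
                               selection = cfg$selection$seed,
                               stacking = cfg$stacking$seed))
      yaml::write_yaml(log, out("run_log.yaml"))
    })
  }

  invisible(list(data = data, feature_table = ft, ranking = ranking,
                 ifs = ifs, cv = cv, model = model,
                 test_metrics = test_metrics, metrics = metrics,
                 config = cfg))
}

#' Reproduce a benchmark run from downloaded FASTA files
#'
#' Convenience recipe for the published uridine-centred benchmark sets
#' (balanced positive/negative FASTA files, 21 or 31 nt): runs the default
#' architecture (PSTNPss + PS3 features, RF + LR stacked under an LR
#' meta-classifier, 5-fold CV) on a downloaded training pair and,
#' optionally, an independent test pair. The benchmark files themselves
#' are external downloads and are not shipped with the package.
#'
#' @param train_pos,train_neg training FASTA paths (positive / negative).
#' @param test_pos,test_neg optional independent-test FASTA paths.
#' @param schemes,bases,folds,seed pipeline controls (defaults give the
#'   reference architecture).
#' @return The [run_pipeline()] result list.
#' @export
run_benchmark <- function(train_pos, train_neg,
                          test_pos = NULL, test_neg = NULL,
                          schemes = c("PSTNPss", "PS3"),
                          bases = c("RF", "LR"), folds = 5, seed = 1) {
  cfg <- list(input = list(pos = train_pos, neg = train_neg),
              schemes = schemes,
              stacking = list(bases = bases, folds = folds, seed = seed))
  if (!is.null(test_pos)) cfg$test <- list(pos = test_pos, neg = test_neg)
  run_pipeline(cfg)
}
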