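#' Resolve the feature list for a training regime
#'
#' Three regimes control how much the model leans on other predictors:
#' * `CTI` — clinical-trained tools included: every feature in the catalog;
#' * `CTE` — clinical-trained tools excluded: drops `vep_score` features
#'   whose tool was trained on clinical labels;
#' * `SP` — single predictor: drops every `vep_score` feature, leaving only
#'   primary biological signal.
#'
#' By construction SP ⊆ CTE ⊆ CTI.
#'
#' @param meta Feature metadata tibble (`feature`, `category`,
#'   `clinical_trained`).
#' @param regime `"CTI"`, `"CTE"` or `"SP"`.
#' @return List with `regime` and `features` (character vector, catalog
#'   order).
#' @export
resolve_feature_config <- function(meta, regime = c("CTI", "CTE", "SP")) {
  regime <- match.arg(regime)
  keep <- switch(
    regime,
    CTI = rep(TRUE, nrow(meta)),
    CTE = !(meta$category == "vep_score" &
              dplyr::coalesce(meta$clinical_trained, FALSE)),
    SP = meta$category != "vep_score"
  )
  features <- meta$feature[keep]
  if (length(features) == 0) {
    stop("regime ", regime, " resolves to an empty feature set", call. = FALSE)
  }
  list(regime = regime, features = features)
}

# Seeded random draw from the hyperparameter search space. The grid bounds
# are fixed here (documented defaults); tree depth and leaf regularization
# dominate fit capacity on tabular variant features.
draw_params <- function() {
  list(
    objective = "binary:logistic",
    eval_metric = "auc",
    max_depth = sample(3:8, 1),
    eta = exp(stats::runif(1, log(0.02), log(0.3))),
    min_child_weight = sample(1:10, 1),
    subsample = stats::runif(1, 0.6, 1),
    colsample_bytree = stats::runif(1, 0.6, 1),
    lambda = stats::runif(1, 0, 5),
    nthread = 1
  )
}

#' Train a binary variant-effect classifier
#'
#' Gradient-boosted trees (\pkg{xgboost}) on a labeled dataset restricted to
#' one feature regime. The data are split stratified-by-label into
#' train/holdout (default 90/10, seeded), hyperparameters are chosen by
#' seeded random search maximizing holdout AUC over `trials` candidates
#' (early stopping on the holdout), the final model is refit on the training
#' split with the best configuration, and the decision threshold is the
#' balanced-accuracy-optimal cut of holdout scores. Proxy-benign sample
#' weights are applied throughout. The manifest records seed, trials, split,
#' parameters and the training-split variant keys; [predict.vep_model()]
#' refuses to score those keys, eliminating variant-level circularity.
#'
#' @param dataset Labeled dataset tibble (`variant_key`, `label`,
#'   `sample_weight`).
#' @param features Wide feature tibble covering the dataset's variant keys.
#' @param config Feature config from [resolve_feature_config()].
#' @param split Training fraction (default 0.9).
#' @param trials Hyperparameter search trials (default 50).
#' @param seed Integer seed; the full train–predict path is bit-stable
#'   given it.
#' @param nrounds Maximum boosting rounds per trial (early stopped).
#' @return A `vep_model` object: booster, feature list, decision threshold,
#'   holdout metrics and training manifest.
#' @export
train_classifier <- function(dataset, features, config, split = 0.9,
                             trials = 50L, seed = 1L, nrounds = 400L) {
  stopifnot(all(c("variant_key", "label") %in% names(dataset)))
  if (nrow(dataset) < 20) {
    stop("at least 20 labeled records are required", call. = FALSE)
  }
  if (length(unique(dataset$label)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  missing_keys <- setdiff(dataset$variant_key, features$variant_key)
  if (length(missing_keys) > 0) {
    stop("dataset variants absent from feature matrix: ",
         paste(utils::head(missing_keys, 3), collapse = ", "), call. = FALSE)
  }
  missing_feats <- setdiff(config$features, names(features))
  if (length(missing_feats) > 0) {
    stop("feature matrix lacks column(s): ",
         paste(missing_feats, collapse = ", "), call. = FALSE)
  }
  weights <- if ("sample_weight" %in% names(dataset)) {
    dataset$sample_weight
  } else rep(1, nrow(dataset))

  feat <- features[match(dataset$variant_key, features$variant_key),
                   config$features, drop = FALSE]
  x <- as.matrix(feat)
  y <- dataset$label

  res <- withr::with_seed(seed, {
    idx_test <- unlist(lapply(split(seq_along(y), y), function(idx) {
      sample(idx, max(1L, round(length(idx) * (1 - split))))
    }), use.names = FALSE)
    idx_train <- setdiff(seq_along(y), idx_test)
    dtrain <- xgboost::xgb.DMatrix(x[idx_train, , drop = FALSE],
                                   label = y[idx_train],
                                   weight = weights[idx_train], missing = NA)
    dtest <- xgboost::xgb.DMatrix(x[idx_test, , drop = FALSE],
                                  label = y[idx_test],
                                  weight = weights[idx_test], missing = NA)
    best <- NULL
    for (i in seq_len(trials)) {
      params <- draw_params()
      params$seed <- seed + i
      fit <- xgboost::xgb.train(
        params = params, data = dtrain, nrounds = nrounds,
        evals = list(test = dtest), early_stopping_rounds = 25L, verbose = 0
      )
      auc_i <- rank_auc(stats::predict(fit, dtest), y[idx_test])
      if (is.null(best) || auc_i > best$auc) {
        best <- list(params = params, auc = auc_i,
                     nrounds = xgboost::xgb.attr(fit, "best_iteration"))
      }
    }
    final_rounds <- max(1L, as.integer(best$nrounds))
    booster <- xgboost::xgb.train(
      params = best$params, data = dtrain, nrounds = final_rounds, verbose = 0
    )
    holdout_scores <- stats::predict(booster, dtest)
    threshold <- optimize_threshold(holdout_scores, y[idx_test])
    list(
      booster = booster,
      threshold = as.numeric(threshold),
      metrics = list(
        auc = rank_auc(holdout_scores, y[idx_test]),
        accuracy = mean((holdout_scores >= threshold) == (y[idx_test] == 1)),
        balanced_accuracy = attr(threshold, "balanced_accuracy")
      ),
      params = best$params,
      idx_train = idx_train
    )
  })

  structure(
    list(
      booster = res$booster,
      features = config$features,
      regime = config$regime,
      decision_threshold = res$threshold,
      metrics = res$metrics,
      manifest = list(
        seed = seed, trials = trials, split = split,
        params = res$params,
        n_train = length(res$idx_train),
        excluded_training_keys = sort(dataset$variant_key[res$idx_train])
      )
    ),
    class = "vep_model"
  )
}

#' @export
print.vep_model <- function(x, ...) {
  cat(sprintf(
    "<vep_model> regime=%s  features=%d  threshold=%.4f  holdout AUC=%.4f\n",
    x$regime, length(x$features), x$decision_threshold, x$metrics$auc
  ))
  cat(sprintf("  trained on %d variants (excluded from prediction)\n",
              x$manifest$n_train))
  invisible(x)
}

#' Score variants with a trained classifier
#'
#' Variants recorded in the model's training manifest are never scored: they
#' come back flagged `EXCLUDED_TRAINING` with an `NA` score, so downstream
#' benchmarks and classifications cannot recycle training variants. Rows
#' with entirely missing features are still scored (trees route missing
#' values natively).
#'
#' @param object A `vep_model`.
#' @param features Wide feature tibble containing at least the model's
#'   feature columns.
#' @param ... Unused.
#' @return Tibble (`variant_key`, `score`, `class`, `excluded`, `flag`).
#' @export
predict.vep_model <- function(object, features, ...) {
  missing_feats <- setdiff(object$features, names(features))
  if (length(missing_feats) > 0) {
    stop("feature matrix lacks column(s): ",
         paste(missing_feats, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(features[, object$features, drop = FALSE])
  scores <- stats::predict(object$booster,
                           xgboost::xgb.DMatrix(x, missing = NA))
  excluded <- features$variant_key %in%
    object$manifest$excluded_training_keys
  scores[excluded] <- NA_real_
  tibble::tibble(
    variant_key = features$variant_key,
    score = scores,
    class = dplyr::case_when(
      excluded ~ NA_character_,
      scores >= object$decision_threshold ~ "damaging",
      TRUE ~ "neutral"
    ),
    excluded = excluded,
    flag = ifelse(excluded, "EXCLUDED_TRAINING", NA_character_)
  )
}

#' Per-feature attribution of model predictions
#'
#' Additive per-prediction contributions (TreeSHAP) averaged as absolute
#' values over the supplied variants, ranked, with category totals attached.
#' Category totals partition the per-feature totals exactly.
#'
#' @param model A `vep_model`.
#' @param features Wide feature tibble to explain.
#' @param meta Optional feature metadata (adds a `category` column).
#' @return Tibble (`feature`, `category`, `mean_abs_contrib`, `rank`),
#'   sorted by decreasing contribution; attribute `"by_category"` holds the
#'   grouped totals.
#' @export
feature_attribution <- function(model, features, meta = NULL) {
  x <- as.matrix(features[, model$features, drop = FALSE])
  contrib <- stats::predict(model$booster,
                            xgboost::xgb.DMatrix(x, missing = NA),
                            predcontrib = TRUE)
  contrib <- contrib[, model$features, drop = FALSE]  # drop BIAS column
  out <- tibble::tibble(
    feature = model$features,
    mean_abs_contrib = unname(colMeans(abs(contrib)))
  )
  if (!is.null(meta)) {
    out <- dplyr::left_join(out, meta[, c("feature", "category")],
                            by = "feature")
  } else {
    out$category <- NA_character_
  }
  out <- out[order(-out$mean_abs_contrib, out$feature), ]
  out$rank <- seq_len(nrow(out))
  out <- dplyr::relocate(out, "feature", "category")
  attr(out, "by_category") <- out |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(total_contrib = sum(.data$mean_abs_contrib),
                     n_features = dplyr::n(), .groups = "drop")
  out
}

#' Save a trained model to a directory
#'
#' Writes the booster (native format) plus a `manifest.json` carrying seed,
#' trials, split, threshold, feature list and excluded training keys.
#'
#' @param model A `vep_model`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_vep_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  xgboost::xgb.save(model$booster, file.path(dir, "booster.ubj"))
  manifest <- c(
    model$manifest[c("seed", "trials", "split", "n_train",
                     "excluded_training_keys")],
    list(
      params = model$manifest$params,
      regime = model$regime,
      features = model$features,
      decision_threshold = model$decision_threshold,
      metrics = model$metrics
    )
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a trained model saved by [save_vep_model()]
#'
#' @param dir Model directory.
#' @return A `vep_model`.
#' @export
load_vep_model <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  structure(
    list(
      booster = xgboost::xgb.load(file.path(dir, "booster.ubj")),
      features = manifest$features,
      regime = manifest$regime,
      decision_threshold = manifest$decision_threshold,
      metrics = as.list(manifest$metrics),
      manifest = list(
        seed = manifest$seed, trials = manifest$trials,
        split = manifest$split, params = as.list(manifest$params),
        n_train = manifest$n_train,
        excluded_training_keys = manifest$excluded_training_keys
      )
    ),
    class = "vep_model"
  )
}
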