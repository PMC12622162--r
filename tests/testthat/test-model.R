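catalog_fixture <- function() {
  tibble::tibble(
    feature = sprintf("f%02d", 1:10),
    category = c(rep("vep_score", 3), rep("conservation", 3),
                 rep("plm", 2), rep("gene_level", 2)),
    clinical_trained = c(TRUE, FALSE, FALSE, rep(FALSE, 7)),
    tool_id = c("t1", "t2", "t3", rep(NA, 7))
  )
}

test_that("feature regimes apply the subset rules exactly", {
  meta <- catalog_fixture()
  cti <- resolve_feature_config(meta, "CTI")
  cte <- resolve_feature_config(meta, "CTE")
  sp <- resolve_feature_config(meta, "SP")
  expect_length(cti$features, 10)
  expect_length(cte$features, 9)
  expect_length(sp$features, 7)
  # SP ⊆ CTE ⊆ CTI
  expect_true(all(sp$features %in% cte$features))
  expect_true(all(cte$features %in% cti$features))

  # no vep features: all regimes identical
  novep <- meta[meta$category != "vep_score", ]
  expect_equal(resolve_feature_config(novep, "SP")$features,
               resolve_feature_config(novep, "CTI")$features)
  # vep-only catalog under SP is empty -> error
  expect_error(
    resolve_feature_config(meta[meta$category == "vep_score", ], "SP"),
    "empty feature set"
  )
})

test_that("regime nesting holds on randomized catalogs", {
  withr::with_seed(12, {
    cats <- c("vep_score", "conservation", "structural", "plm", "gene_level")
    for (i in 1:10) {
      n <- sample(5:30, 1)
      meta <- tibble::tibble(
        feature = sprintf("f%d", seq_len(n)),
        category = sample(cats, n, replace = TRUE),
        clinical_trained = runif(n) < 0.3,
        tool_id = NA_character_
      )
      meta$clinical_trained[meta$category != "vep_score"] <- FALSE
      if (all(meta$category == "vep_score")) next
      sp <- resolve_feature_config(meta, "SP")$features
      cte <- resolve_feature_config(meta, "CTE")$features
      cti <- resolve_feature_config(meta, "CTI")$features
      expect_true(all(sp %in% cte) && all(cte %in% cti))
      expect_equal(length(cti) - sum(meta$category == "vep_score"),
                   length(sp))
    }
  })
})

test_that("threshold optimization matches a hand-computed sweep", {
  thr <- optimize_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(as.numeric(thr), 0.5)
  expect_equal(attr(thr, "balanced_accuracy"), 1.0)

  # fully interleaved identical scores: balanced accuracy 0.5
  thr2 <- optimize_threshold(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(attr(thr2, "balanced_accuracy"), 0.5)

  # monotone rescaling preserves the partition
  s <- c(0.2, 0.4, 0.35, 0.9, 0.7, 0.1)
  l <- c(0, 1, 0, 1, 1, 0)
  t1 <- optimize_threshold(s, l)
  t2 <- optimize_threshold(exp(5 * s), l)
  expect_equal(s >= as.numeric(t1), exp(5 * s) >= as.numeric(t2))

  expect_error(optimize_threshold(c(0.1, 0.9), c(1, 1)), "both classes")
})

sim_fixture <- function(seed = 7) {
  cfg <- sim_config(seed = seed)
  ds <- simulate_labeled_variants(cfg)
  fm <- simulate_feature_matrix(ds, cfg)
  list(cfg = cfg, ds = ds, fm = fm)
}

test_that("training on separable synthetic data reaches high holdout AUC", {
  fx <- sim_fixture()
  config <- resolve_feature_config(fx$fm$meta, "CTI")
  model <- train_classifier(fx$ds, fx$fm$features, config, trials = 8,
                            seed = 7)
  expect_gte(model$metrics$auc, 0.95)
  expect_true(model$decision_threshold > 0 && model$decision_threshold < 1)

  # training is deterministic: identical run, identical seed
  model2 <- train_classifier(fx$ds, fx$fm$features, config, trials = 8,
                             seed = 7)
  expect_identical(model$metrics$auc, model2$metrics$auc)
  expect_identical(predict(model, fx$fm$features)$score,
                   predict(model2, fx$fm$features)$score)
})

test_that("permuted labels give chance-level holdout AUC across seeds", {
  fx <- sim_fixture()
  config <- resolve_feature_config(fx$fm$meta, "CTI")
  hits <- 0
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    ds_null <- fx$ds
    ds_null$label <- withr::with_seed(2000 + s, sample(ds_null$label))
    m <- train_classifier(ds_null, fx$fm$features, config, trials = 2,
                          seed = s)
    if (m$metrics$auc >= 0.40 && m$metrics$auc <= 0.60) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("training rejects degenerate inputs", {
  fx <- sim_fixture()
  config <- resolve_feature_config(fx$fm$meta, "CTI")
  single <- fx$ds; single$label <- 1L
  expect_error(train_classifier(single, fx$fm$features, config, seed = 1),
               "both classes")
  expect_error(train_classifier(fx$ds[1:10, ], fx$fm$features, config,
                                seed = 1),
               "at least 20")
})

test_that("prediction refuses manifest training variants and is repeatable", {
  fx <- sim_fixture()
  config <- resolve_feature_config(fx$fm$meta, "CTI")
  model <- train_classifier(fx$ds, fx$fm$features, config, trials = 2,
                            seed = 7)
  pred <- predict(model, fx$fm$features)
  train_keys <- model$manifest$excluded_training_keys
  expect_true(all(is.na(pred$score[pred$variant_key %in% train_keys])))
  expect_true(all(pred$flag[pred$variant_key %in% train_keys] ==
                    "EXCLUDED_TRAINING"))
  expect_true(all(!is.na(pred$score[!pred$variant_key %in% train_keys])))
  expect_identical(pred$score, predict(model, fx$fm$features)$score)

  # an all-missing feature row is still scored
  row_na <- fx$fm$features[!fx$fm$features$variant_key %in% train_keys, ][1, ]
  row_na[, -1] <- NA_real_
  expect_false(is.na(predict(model, row_na)$score))

  expect_error(predict(model, fx$fm$features[, 1:3]), "lacks column")
})

test_that("attribution ranks informative features first and partitions totals", {
  fx <- sim_fixture()
  config <- resolve_feature_config(fx$fm$meta, "CTI")
  model <- train_classifier(fx$ds, fx$fm$features, config, trials = 4,
                            seed = 7)
  att <- feature_attribution(model, fx$fm$features, fx$fm$meta)
  k <- length(fx$fm$informative)
  top_k <- att$feature[seq_len(k)]
  recovered <- length(intersect(top_k, fx$fm$informative)) / k
  expect_gte(recovered, 0.8)

  by_cat <- attr(att, "by_category")
  expect_equal(sum(by_cat$total_contrib), sum(att$mean_abs_contrib))

  # single informative feature dominates; constant feature attributes ~0
  withr::with_seed(3, {
    n <- 400
    ds1 <- tibble::tibble(variant_key = sprintf("v%d", 1:n),
                          label = rep(c(1L, 0L), n / 2), sample_weight = 1)
    feats <- tibble::tibble(
      variant_key = ds1$variant_key,
      f1 = rnorm(n) + 3 * ds1$label,
      f2 = rnorm(n),
      f3 = 1.0
    )
  })
  meta1 <- tibble::tibble(feature = c("f1", "f2", "f3"),
                          category = "conservation",
                          clinical_trained = FALSE, tool_id = NA)
  m1 <- train_classifier(ds1, feats, resolve_feature_config(meta1, "CTI"),
                         trials = 2, seed = 4)
  att1 <- feature_attribution(m1, feats, meta1)
  expect_equal(att1$feature[1], "f1")
  expect_equal(att1$mean_abs_contrib[att1$feature == "f3"], 0)
})

test_that("models survive a save/load round trip", {
  fx <- sim_fixture()
  config <- resolve_feature_config(fx$fm$meta, "SP")
  model <- train_classifier(fx$ds, fx$fm$features, config, trials = 2,
                            seed = 7)
  dir <- withr::local_tempdir()
  save_vep_model(model, dir)
  back <- load_vep_model(dir)
  expect_equal(predict(back, fx$fm$features)$score,
               predict(model, fx$fm$features)$score)
  expect_equal(back$decision_threshold, model$decision_threshold)
  expect_equal(back$manifest$excluded_training_keys,
               model$manifest$excluded_training_keys)

  g <- glance(model)
  expect_equal(g$regime, "SP")
  expect_s3_class(tidy(model), "tbl_df")
})
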