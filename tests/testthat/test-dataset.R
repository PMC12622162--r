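make_calibration_fixture <- function(seed = 21, n_per_class = 20,
                                     sd = 0.1, permute = FALSE) {
  withr::with_seed(seed, {
    keys <- sprintf("1:%d:A:T", seq_len(2 * n_per_class))
    labels <- stats::setNames(rep(c(1L, 0L), each = n_per_class), keys)
    scores <- stats::setNames(
      c(rnorm(n_per_class, 1, sd), rnorm(n_per_class, 0, sd)), keys
    )
    if (permute) labels[] <- sample(labels)
  })
  list(study = list(study_id = "S1", gene = "G", scores = scores),
       labels = labels)
}

test_that("well-separated assay studies are accepted with perfect AUC", {
  fx <- make_calibration_fixture()
  cal <- calibrate_assay_study(fx$study, fx$labels, alpha = 0.05,
                               n_studies = 274)
  expect_true(cal$accepted)
  expect_equal(cal$auc, 1.0)
  expect_lt(cal$p_value, 0.05 / 274)
  # threshold separates the two score clouds
  expect_gt(cal$binarization_threshold, 0.3)
  expect_lt(cal$binarization_threshold, 0.7)
})

test_that("permuted labels reject the study in at least 95% of permutations", {
  rejected <- 0
  for (i in 1:200) {
    fx <- make_calibration_fixture(seed = 1000 + i, permute = TRUE)
    cal <- calibrate_assay_study(fx$study, fx$labels, alpha = 0.05,
                                 n_studies = 274)
    if (!cal$accepted) rejected <- rejected + 1
  }
  expect_gte(rejected / 200, 0.95)
})

test_that("insufficient overlap is a rejection reason, not an exception", {
  fx <- make_calibration_fixture(n_per_class = 2)
  cal <- calibrate_assay_study(fx$study, fx$labels, min_overlap = 10)
  expect_false(cal$accepted)
  expect_equal(cal$reason, "insufficient_overlap")
})

test_that("calibration is invariant to strictly monotone score transforms", {
  fx <- make_calibration_fixture()
  direct <- calibrate_assay_study(fx$study, fx$labels, n_studies = 10)
  warped <- fx$study
  warped$scores <- exp(3 * warped$scores) + 5
  trans <- calibrate_assay_study(warped, fx$labels, n_studies = 10)
  expect_equal(trans$auc, direct$auc)
  expect_equal(trans$p_value, direct$p_value)
  expect_equal(trans$accepted, direct$accepted)
})

test_that("inverted assay scales are flipped and then accepted", {
  fx <- make_calibration_fixture()
  flipped <- fx$study
  flipped$scores <- -flipped$scores
  cal <- calibrate_assay_study(flipped, fx$labels, n_studies = 10)
  expect_true(cal$accepted)
  expect_equal(cal$orientation, "lower_is_damaging")
  expect_equal(cal$auc, 1.0)
})

test_that("proxy weights follow the log10 min-max formula", {
  expect_equal(compute_proxy_weights(c(1e-5, 1e-3, 1e-1)), c(0, 0.5, 1))
  expect_equal(compute_proxy_weights(c(1e-4, 1e-2)), c(0, 1))
  expect_equal(compute_proxy_weights(c(5e-3, 5e-3)), c(1, 1))
  expect_error(compute_proxy_weights(c(0, 0.5)), "strictly in")
  expect_error(compute_proxy_weights(c(0.5, 1)), "strictly in")
  # order-preserving in AF
  withr::with_seed(8, {
    af <- sort(runif(50, 1e-6, 0.5))
    w <- compute_proxy_weights(af)
    expect_true(all(diff(w) >= 0))
  })
})

test_that("splice-confounded records are removed by strict inequality", {
  rec <- tibble::tibble(variant_key = c("v1", "v2", "v3"), gene = "G",
                        label = 1L)
  scores <- c(v1 = 0.5, v2 = 0.1)
  out <- exclude_splice_confounded(rec, scores)
  expect_setequal(out$variant_key, c("v2", "v3"))  # v3 has no score: kept
  # exactly at the cutoff: kept
  out2 <- exclude_splice_confounded(rec, c(v1 = 0.2))
  expect_setequal(out2$variant_key, c("v1", "v2", "v3"))
  # empty score map keeps everything
  out3 <- exclude_splice_confounded(rec, numeric(0))
  expect_equal(nrow(out3), 3)
})

test_that("per-gene balancing downsamples the majority class exactly", {
  rec <- tibble::tibble(
    variant_key = sprintf("v%d", 1:12),
    gene = c(rep("G", 8), rep("H", 4)),
    label = c(rep(1L, 5), rep(0L, 3), rep(1L, 4))
  )
  out <- balance_per_gene(rec, seed = 3)
  counts <- table(out$gene, out$label)
  expect_equal(unname(counts["G", ]), c(3, 3))
  expect_false("H" %in% out$gene)  # single-class gene dropped

  kept <- balance_per_gene(rec, seed = 3, single_class_policy = "keep_capped")
  expect_true("H" %in% kept$gene)
  expect_equal(sum(kept$gene == "H"), 3)  # capped at median balanced size

  # already balanced gene is a fixed point under any seed
  bal <- rec[rec$gene == "G", ][c(1:3, 6:8), ]
  expect_identical(balance_per_gene(bal, seed = 1),
                   balance_per_gene(bal, seed = 99))
  expect_equal(nrow(balance_per_gene(bal, seed = 1)), 6)

  # deterministic for fixed seed
  expect_identical(balance_per_gene(rec, seed = 11),
                   balance_per_gene(rec, seed = 11))
  expect_equal(nrow(balance_per_gene(rec[0, ], seed = 1)), 0)
})

test_that("functional dataset merge applies precedence and drops conflicts", {
  curated <- tibble::tibble(variant_key = "v1", gene = "G", label = 1L)
  text <- tibble::tibble(variant_key = c("v1", "v2", "v3", "v4"), gene = "G",
                         label = c(0L, 0L, 1L, 0L))
  ds <- build_functional_dataset(curated = curated, text_mined = text,
                                 seed = 1)
  # curated label wins over text_mined for v1
  expect_equal(ds$label[ds$variant_key == "v1"], 1L)
  expect_equal(ds$source[ds$variant_key == "v1"], "curated")

  # within-tier conflicts are dropped outright
  conflicted <- tibble::tibble(
    variant_key = c("v9", "v9", "v2", "v3", "v4", "v5"), gene = "G",
    label = c(1L, 0L, 0L, 1L, 1L, 0L)
  )
  ds2 <- build_functional_dataset(curated = conflicted, seed = 1)
  expect_false("v9" %in% ds2$variant_key)
})

test_that("proxy benigns overlapping labeled sources are excluded", {
  curated <- tibble::tibble(variant_key = c("v1", "v2"), gene = "G",
                            label = c(1L, 0L))
  proxy <- tibble::tibble(variant_key = c("v1", "v3"), gene = "G",
                          af = c(1e-3, 1e-3))
  ds <- build_functional_dataset(curated = curated, proxy_benign = proxy,
                                 seed = 1)
  expect_equal(sum(ds$variant_key == "v1"), 1)
  expect_equal(ds$source[ds$variant_key == "v1"], "curated")
  expect_false(any(duplicated(ds$variant_key)))
  # empty sources give an empty dataset
  expect_equal(nrow(build_functional_dataset()), 0)
})

test_that("accepted MAVE studies are binarized at their thresholds", {
  fx <- make_calibration_fixture(n_per_class = 15)
  cal <- calibrate_assay_study(fx$study, fx$labels, n_studies = 5)
  ds <- build_functional_dataset(mave = cal, seed = 1)
  expect_true(all(ds$source == "mave"))
  # labels recover the generating separation on the scored variants
  truth <- fx$labels[ds$variant_key]
  expect_gte(mean(ds$label == truth), 0.95)

  # rejected studies contribute nothing
  rej <- cal; rej$accepted <- FALSE
  expect_equal(nrow(build_functional_dataset(mave = rej, seed = 1)), 0)
})

test_that("clinical dataset applies star, class, splice and balance filters", {
  rec <- tibble::tibble(
    variant_key = sprintf("v%d", 1:8),
    gene = "G",
    stars = c(1L, 3L, 2L, 2L, 2L, 0L, 2L, 2L),
    class = c("Pathogenic", "Likely benign", "Pathogenic", "Benign",
              "Uncertain significance", "Benign", "Pathogenic",
              "Likely pathogenic")
  )
  expect_message(
    ds <- build_clinical_dataset(rec, seed = 1),
    "skipped"
  )
  # v1 (1-star) and v6 (0-star) excluded; v5 (VUS) skipped
  expect_false(any(c("v1", "v5", "v6") %in% ds$variant_key))
  # 3-star likely benign retained with label 0
  expect_equal(ds$label[ds$variant_key == "v2"], 0L)
  # balanced: 2 benign available -> 2 pathogenic kept
  expect_equal(as.integer(table(ds$label)), c(2L, 2L))

  # splice-confounded pathogenic removed before balancing
  ds2 <- suppressMessages(build_clinical_dataset(
    rec, splice_scores = c(v3 = 0.9), seed = 1
  ))
  expect_false("v3" %in% ds2$variant_key)
})

test_that("balancing leaves equal class counts in every retained gene", {
  withr::with_seed(17, {
    rec <- tibble::tibble(
      variant_key = sprintf("v%d", 1:400),
      gene = sample(sprintf("G%d", 1:12), 400, replace = TRUE),
      label = rbinom(400, 1, 0.35)
    )
  })
  out <- balance_per_gene(rec, seed = 2)
  per_gene <- table(out$gene, out$label)
  expect_true(all(per_gene[, 1] == per_gene[, 2]))
  expect_false(any(duplicated(out$variant_key)))
})
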