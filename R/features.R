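#' Protein-language-model-derived substitution features
#'
#' Quantifies how a substitution perturbs a protein language model's view of
#' the sequence, from per-position log-likelihoods (natural log) and a mean
#' embedding computed for the wild-type and mutant sequences:
#' * `mean_loglik_diff` = mean(wt loglik) − mean(mut loglik): positive when
#'   the mutant sequence is less plausible overall;
#' * `perplexity_diff` = exp(−mean(mut loglik)) − exp(−mean(wt loglik)):
#'   positive when the mutant is more surprising;
#' * `embedding_shift` = Euclidean distance between mean embeddings;
#' * `site_loglik_diff` = wt loglik − mut loglik at the substituted site.
#'
#' The three difference features are antisymmetric in (wt, mut); the
#' embedding shift is symmetric. All four are exactly zero when the two
#' sequence statistics are identical.
#'
#' @param wt,mut Sequence statistics: lists with `loglik` (numeric vector,
#'   one entry per position) and `embedding` (numeric vector of fixed
#'   dimension). Any deterministic provider (a real protein language model or
#'   a synthetic stand-in) can produce them.
#' @param site 1-based position of the substitution.
#' @return One-row tibble with the four features.
#' @export
plm_feature_set <- function(wt, mut, site) {
  if (length(wt$loglik) != length(mut$loglik)) {
    stop("wild-type and mutant sequences must have equal length", call. = FALSE)
  }
  if (length(wt$embedding) != length(mut$embedding)) {
    stop("embedding dimensions must match", call. = FALSE)
  }
  if (site < 1 || site > length(wt$loglik)) {
    stop("site out of sequence range", call. = FALSE)
  }
  tibble::tibble(
    mean_loglik_diff = mean(wt$loglik) - mean(mut$loglik),
    perplexity_diff = exp(-mean(mut$loglik)) - exp(-mean(wt$loglik)),
    embedding_shift = sqrt(sum((wt$embedding - mut$embedding)^2)),
    site_loglik_diff = wt$loglik[site] - mut$loglik[site]
  )
}

#' Detect features with class-biased (informative) missingness
#'
#' A feature whose missingness rate differs between classes leaks label
#' information through its missing-value pattern. Each feature's per-class
#' missingness is compared with a two-proportion test; features with
#' p < `alpha` are flagged for model-based imputation. Fully missing
#' features are flagged unconditionally.
#'
#' @param features Wide feature tibble (`variant_key` + feature columns).
#' @param labels Binary labels aligned to the rows of `features`.
#' @param alpha Significance level (default 0.01).
#' @return Tibble (`feature`, `miss_rate_pos`, `miss_rate_neg`, `p_value`,
#'   `flagged`, `reason`), one row per feature.
#' @export
flag_biased_missingness <- function(features, labels, alpha = 0.01) {
  stopifnot(nrow(features) == length(labels))
  feats <- setdiff(names(features), "variant_key")
  pos <- labels == 1
  dplyr::bind_rows(purrr::map(feats, function(f) {
    m <- is.na(features[[f]])
    x <- c(sum(m[pos]), sum(m[!pos]))
    n <- c(sum(pos), sum(!pos))
    if (all(m)) {
      return(tibble::tibble(
        feature = f, miss_rate_pos = 1, miss_rate_neg = 1,
        p_value = NA_real_, flagged = TRUE, reason = "fully_missing"
      ))
    }
    p <- if (all(x == 0) || all(x == n)) 1 else {
      suppressWarnings(stats::prop.test(x, n)$p.value)
    }
    tibble::tibble(
      feature = f, miss_rate_pos = x[1] / n[1], miss_rate_neg = x[2] / n[2],
      p_value = p, flagged = is.finite(p) && p < alpha,
      reason = ifelse(is.finite(p) && p < alpha, "biased_missingness",
                      NA_character_)
    )
  }))
}

#' Impute flagged features with gradient-boosted regressors
#'
#' For every flagged feature, a gradient-boosted tree regressor is trained on
#' the unlabeled background rows where the feature is observed, using all
#' remaining features as predictors (trees handle missing predictors
#' natively), and its predictions fill the missing cells of the labeled
#' matrix. Labels are never passed in, so the imputation cannot leak class
#' information; observed cells are never altered. Imputed cells are recorded
#' in the `"imputed_cells"` attribute.
#'
#' @param features Wide feature tibble to impute (`variant_key` + columns).
#' @param flagged Character vector of feature names to impute.
#' @param background Wide feature tibble of unlabeled variants sharing the
#'   feature catalog.
#' @param seed Integer seed (regressor training is deterministic given it).
#' @param nrounds Boosting rounds per regressor.
#' @return The imputed feature tibble, with attribute `"imputed_cells"`
#'   (tibble `variant_key`, `feature`).
#' @export
impute_features <- function(features, flagged, background, seed = 1L,
                            nrounds = 400L) {
  feats <- setdiff(names(features), "variant_key")
  absent <- setdiff(flagged, feats)
  if (length(absent) > 0) {
    stop("flagged feature(s) absent from catalog: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (!setequal(feats, setdiff(names(background), "variant_key"))) {
    stop("background must share the feature catalog", call. = FALSE)
  }
  imputed <- list()
  for (f in flagged) {
    target_missing <- is.na(features[[f]])
    if (!any(target_missing)) next
    obs <- !is.na(background[[f]])
    if (!any(obs)) {
      stop("flagged feature '", f,
           "' has zero observed background rows", call. = FALSE)
    }
    predictors <- setdiff(feats, f)
    xb <- as.matrix(background[obs, predictors, drop = FALSE])
    yb <- background[[f]][obs]
    dtrain <- xgboost::xgb.DMatrix(xb, label = yb, missing = NA)
    booster <- withr::with_seed(seed, xgboost::xgb.train(
      params = list(objective = "reg:squarederror", max_depth = 6,
                    eta = 0.1, nthread = 1, seed = seed),
      data = dtrain, nrounds = nrounds, verbose = 0
    ))
    xm <- as.matrix(features[target_missing, predictors, drop = FALSE])
    features[[f]][target_missing] <-
      stats::predict(booster, xgboost::xgb.DMatrix(xm, missing = NA))
    imputed[[f]] <- tibble::tibble(
      variant_key = features$variant_key[target_missing], feature = f
    )
  }
  attr(features, "imputed_cells") <- dplyr::bind_rows(imputed)
  features
}
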