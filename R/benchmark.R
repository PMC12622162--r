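#' Area under the ROC curve
#'
#' Mann–Whitney formulation: the probability that a random positive outscores
#' a random negative, with ties contributing 1/2. Equal to the trapezoidal
#' integral of the ROC curve, and invariant under strictly monotone score
#' transforms.
#'
#' @param scores Numeric scores (higher = more damaging/pathogenic).
#' @param labels Binary labels (1 = positive class).
#' @param na_rm Drop pairs with missing score or label first.
#' @return AUC in \[0, 1\].
#' @export
rank_auc <- function(scores, labels, na_rm = TRUE) {
  if (na_rm) {
    keep <- !is.na(scores) & !is.na(labels)
    scores <- scores[keep]; labels <- labels[keep]
  }
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  r <- rank(scores)  # midranks handle ties with weight 1/2
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Smooth-fit R-squared between predictor and assay scores
#'
#' Fits a univariate penalized thin-plate spline of assay score on predictor
#' score (smoothness chosen by generalized cross-validation, \pkg{mgcv}) and
#' returns the fraction of assay-score variance explained. Tool–study pairs
#' with fewer than `min_pairs` complete observations are excluded (returned
#' as `NA` with attribute `reason = "excluded"`); zero-variance assay scores
#' define R² = 0.
#'
#' @param predictor_scores Numeric predictor scores.
#' @param assay_scores Numeric assay scores, same length.
#' @param min_pairs Minimum complete pairs required (default 10).
#' @return R² in \[0, 1\], or excluded-`NA` when below `min_pairs`.
#' @export
smooth_r2 <- function(predictor_scores, assay_scores, min_pairs = 10L) {
  stopifnot(length(predictor_scores) == length(assay_scores))
  keep <- is.finite(predictor_scores) & is.finite(assay_scores)
  x <- predictor_scores[keep]; y <- assay_scores[keep]
  if (length(x) < min_pairs) {
    return(structure(NA_real_, reason = "excluded"))
  }
  if (stats::var(y) == 0) return(0)
  k <- max(3L, min(10L, length(unique(x)) - 1L))
  if (k < 3L) return(0)
  fit <- mgcv::gam(y ~ s(x, k = k), method = "GCV.Cp")
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  min(max(r2, 0), 1)
}

#' Benchmark tools against assay studies
#'
#' For each tool: variants in the tool's effective training set (closure) are
#' masked first, then [smooth_r2()] is computed against every study, and the
#' per-tool mean is taken over studies that met the minimum-pairs rule. Tools
#' with no eligible study are reported as not evaluable (`NA` mean).
#'
#' @param tools Wide tibble: `variant_key` plus one numeric score column per
#'   tool.
#' @param studies List of assay studies (each with `study_id` and named
#'   `scores` vector).
#' @param closure Optional closure tibble from [expand_component_closure()];
#'   `NULL` disables circularity masking.
#' @param min_pairs Minimum complete pairs per tool–study (default 10).
#' @return List with `summary` (tool, mean_r2, n_studies, evaluable) and
#'   `per_study` (tool, study_id, n_pairs, r2, excluded) tibbles.
#' @export
mave_benchmark <- function(tools, studies, closure = NULL, min_pairs = 10L) {
  tool_names <- setdiff(names(tools), "variant_key")
  eff <- if (is.null(closure)) list() else
    stats::setNames(closure$effective, closure$tool_id)
  per_study <- dplyr::bind_rows(purrr::map(tool_names, function(tl) {
    sc <- stats::setNames(tools[[tl]], tools$variant_key)
    if (tl %in% names(eff)) sc[names(sc) %in% eff[[tl]]] <- NA_real_
    dplyr::bind_rows(purrr::map(studies, function(st) {
      keys <- intersect(names(st$scores), names(sc))
      x <- sc[keys]; y <- st$scores[keys]
      n_pairs <- sum(is.finite(x) & is.finite(y))
      r2 <- smooth_r2(x, y, min_pairs = min_pairs)
      tibble::tibble(
        tool = tl, study_id = st$study_id, n_pairs = n_pairs,
        r2 = as.numeric(r2), excluded = is.na(r2)
      )
    }))
  }))
  summary <- per_study |>
    dplyr::group_by(.data$tool) |>
    dplyr::summarise(
      mean_r2 = if (any(!.data$excluded)) {
        mean(.data$r2[!.data$excluded])
      } else NA_real_,
      n_studies = sum(!.data$excluded),
      evaluable = any(!.data$excluded),
      .groups = "drop"
    )
  list(summary = summary, per_study = per_study)
}
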