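#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trained classifier into a feature-importance table
#'
#' Gain-based importance from the fitted booster; for data-dependent SHAP
#' attributions use [feature_attribution()].
#'
#' @param x A `vep_model`.
#' @param ... Unused.
#' @return Tibble (`feature`, `gain`, `frequency`).
#' @export
tidy.vep_model <- function(x, ...) {
  imp <- xgboost::xgb.importance(model = x$booster)
  out <- tibble::tibble(
    feature = imp$Feature, gain = imp$Gain, frequency = imp$Frequency
  )
  # features never used by any split get zero importance
  unused <- setdiff(x$features, out$feature)
  if (length(unused) > 0) {
    out <- dplyr::bind_rows(
      out, tibble::tibble(feature = unused, gain = 0, frequency = 0)
    )
  }
  out
}

#' One-row summary of a trained classifier
#'
#' @param x A `vep_model`.
#' @param ... Unused.
#' @return Tibble with regime, feature count, threshold and holdout metrics.
#' @export
glance.vep_model <- function(x, ...) {
  tibble::tibble(
    regime = x$regime,
    n_features = length(x$features),
    n_train = x$manifest$n_train,
    decision_threshold = x$decision_threshold,
    auc = x$metrics$auc,
    accuracy = x$metrics$accuracy
  )
}

#' Tidy a calibration table into its score intervals
#'
#' @param x An `acmg_calibration`.
#' @param ... Unused.
#' @return The interval tibble (`lower`, `upper`, `n`, `ppv`, `npv`, `lr`,
#'   `evidence`).
#' @export
tidy.acmg_calibration <- function(x, ...) {
  x$intervals
}

#' One-row summary of a calibration table
#'
#' @param x An `acmg_calibration`.
#' @param ... Unused.
#' @return Tibble with calibration size, prior, ceiling and the strongest
#'   evidence reached on each side.
#' @export
glance.acmg_calibration <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    prior = x$prior,
    lr_ceiling = x$lr_ceiling,
    n_intervals = nrow(x$intervals),
    max_lr = max(x$intervals$lr),
    min_lr = min(x$intervals$lr),
    reaches_pp3_strong = any(x$intervals$evidence == "PP3_strong"),
    reaches_bp4_strong = any(x$intervals$evidence == "BP4_strong")
  )
}
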