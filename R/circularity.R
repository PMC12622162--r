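#' Expand the component closure of a tool registry
#'
#' A meta-predictor inherits the training variants of every component tool,
#' recursively. The effective training set of a tool is therefore the union of
#' training sets over all tools reachable from it in the component graph
#' (itself included). Computed as a fixed-point union iteration, which
#' converges in at most `depth(graph)` passes on an acyclic registry.
#'
#' @param registry A `tool_registry` tibble (see [load_tool_registry()]).
#' @return Tibble with columns `tool_id` and `effective` (list of variant
#'   keys), one row per tool.
#' @export
expand_component_closure <- function(registry) {
  validate_registry(registry)
  eff <- stats::setNames(registry$training_variants, registry$tool_id)
  comp <- stats::setNames(registry$components, registry$tool_id)
  repeat {
    changed <- FALSE
    for (t in registry$tool_id) {
      merged <- unique(c(eff[[t]], unlist(eff[comp[[t]]], use.names = FALSE)))
      if (length(merged) != length(eff[[t]])) {
        eff[[t]] <- merged
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  tibble::tibble(
    tool_id = registry$tool_id,
    effective = purrr::map(unname(eff), sort)
  )
}

#' Mask circular predictor scores in a feature matrix
#'
#' Sets to missing every cell (variant, predictor feature) where the variant
#' belongs to the effective training set of the feature's tool, so no model or
#' benchmark ever consumes a score produced by a tool that trained on that
#' variant. Only `vep_score` features are touched; conservation, structural
#' and other feature categories are never masked. Masked cells become
#' ordinary missing values, eligible for downstream imputation.
#'
#' @param features Wide feature tibble: `variant_key` plus one numeric column
#'   per feature.
#' @param meta Feature metadata tibble with columns `feature`, `category`,
#'   and `tool_id` (non-`NA` exactly for `vep_score` features).
#' @param closure Closure tibble from [expand_component_closure()].
#' @return The masked feature tibble. The attribute `"masking_report"` holds
#'   a tibble (`tool_id`, `feature`, `n_masked`) counting newly masked cells
#'   per predictor feature.
#' @export
mask_circular_scores <- function(features, meta, closure) {
  stopifnot("variant_key" %in% names(features))
  vep <- meta[meta$category == "vep_score", , drop = FALSE]
  missing_cols <- setdiff(vep$feature, names(features))
  if (length(missing_cols) > 0) {
    stop("vep_score feature(s) absent from matrix: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(vep$tool_id, closure$tool_id)
  if (length(unknown) > 0) {
    stop("vep_score feature with unknown tool_id: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  eff <- stats::setNames(closure$effective, closure$tool_id)
  report <- purrr::pmap(
    vep[, c("feature", "tool_id")],
    function(feature, tool_id) {
      hit <- features$variant_key %in% eff[[tool_id]] &
        !is.na(features[[feature]])
      features[[feature]][hit] <<- NA_real_
      tibble::tibble(tool_id = tool_id, feature = feature,
                     n_masked = sum(hit))
    }
  )
  attr(features, "masking_report") <- dplyr::bind_rows(report)
  features
}
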