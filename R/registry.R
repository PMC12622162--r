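#' Load a tool registry
#'
#' The registry records, for every variant effect predictor used as a feature,
#' the set of variants it was trained on and the component tools it aggregates
#' (for meta-predictors such as ensemble scores). It is the input to the
#' circularity closure: a variant must not be scored by any tool that saw it
#' — directly or through a component — during training.
#'
#' The JSON schema is a map `tool_id -> {"training_variants": [keys],
#' "components": [tool_ids], "clinical_trained": bool,
#' "training_unknown": bool}`; the last two are optional and default to
#' `FALSE`. Tools flagged `training_unknown` are excluded from benchmarking
#' comparisons but kept as model features.
#'
#' @param path Path to the JSON registry.
#' @return A tibble with columns `tool_id`, `training_variants` (list),
#'   `components` (list), `clinical_trained`, `training_unknown`, of class
#'   `tool_registry`.
#' @export
load_tool_registry <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path)
  as_tool_registry(raw)
}

#' Build a tool registry from a named list
#'
#' @param tools Named list: `tool_id -> list(training_variants, components,
#'   clinical_trained, training_unknown)`.
#' @return A validated `tool_registry` tibble (see [load_tool_registry()]).
#' @export
as_tool_registry <- function(tools) {
  if (length(tools) == 0) {
    reg <- tibble::tibble(
      tool_id = character(0),
      training_variants = list(),
      components = list(),
      clinical_trained = logical(0),
      training_unknown = logical(0)
    )
    class(reg) <- c("tool_registry", class(reg))
    return(reg)
  }
  if (is.null(names(tools)) || any(names(tools) == "")) {
    stop("registry must be a named map of tool ids", call. = FALSE)
  }
  reg <- tibble::tibble(
    tool_id = names(tools),
    training_variants = purrr::map(tools, function(t) {
      unique(as.character(unlist(t$training_variants)))
    }),
    components = purrr::map(tools, function(t) {
      unique(as.character(unlist(t$components)))
    }),
    clinical_trained = purrr::map_lgl(tools, function(t) {
      isTRUE(t$clinical_trained)
    }),
    training_unknown = purrr::map_lgl(tools, function(t) {
      isTRUE(t$training_unknown)
    })
  )
  validate_registry(reg)
  class(reg) <- c("tool_registry", class(reg))
  reg
}

# Validates that all component ids resolve and the component graph is acyclic.
# Cycle detection is an iterative leaf-stripping (Kahn) pass; the tools left
# over when no further leaf can be removed all lie on or feed a cycle, and are
# reported in the error.
validate_registry <- function(reg) {
  unknown <- setdiff(unlist(reg$components), reg$tool_id)
  if (length(unknown) > 0) {
    stop("unknown component tool id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  deps <- stats::setNames(reg$components, reg$tool_id)
  remaining <- reg$tool_id
  repeat {
    leaves <- remaining[purrr::map_lgl(remaining, function(t) {
      length(intersect(deps[[t]], remaining)) == 0
    })]
    if (length(leaves) == 0) break
    remaining <- setdiff(remaining, leaves)
  }
  if (length(remaining) > 0) {
    stop("component graph contains a cycle involving: ",
         paste(sort(remaining), collapse = " -> "), call. = FALSE)
  }
  invisible(reg)
}

#' Write a tool registry to JSON
#'
#' @param registry A `tool_registry` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tool_registry <- function(registry, path) {
  out <- stats::setNames(
    purrr::pmap(registry, function(tool_id, training_variants, components,
                                   clinical_trained, training_unknown, ...) {
      list(
        training_variants = as.list(training_variants),
        components = as.list(components),
        clinical_trained = clinical_trained,
        training_unknown = training_unknown
      )
    }),
    registry$tool_id
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
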