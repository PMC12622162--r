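#' Balanced accuracy of a score cut
#'
#' @param scores Numeric scores (higher = more damaging/pathogenic).
#' @param labels Binary labels (1 = damaging/pathogenic).
#' @param cut Decision cut; `scores >= cut` predicts the positive class.
#' @return Balanced accuracy (mean of sensitivity and specificity).
#' @export
balanced_accuracy <- function(scores, labels, cut) {
  pred <- scores >= cut
  sens <- mean(pred[labels == 1])
  spec <- mean(!pred[labels == 0])
  (sens + spec) / 2
}

# Exhaustive sweep over candidate cuts: midpoints of adjacent sorted unique
# scores, plus one cut below the minimum and one above the maximum (all-
# positive / all-negative decisions). Tie policy: "smallest" returns the
# smallest qualifying cut, "midpoint" the midpoint of the tying cuts.
sweep_balanced_accuracy <- function(scores, labels,
                                    ties = c("smallest", "midpoint")) {
  ties <- match.arg(ties)
  if (length(unique(labels)) < 2) {
    stop("both classes must be present to optimize a threshold", call. = FALSE)
  }
  s <- sort(unique(scores))
  cuts <- if (length(s) == 1) s else {
    c(s[1] - 1, (s[-1] + s[-length(s)]) / 2, s[length(s)] + 1)
  }
  ba <- vapply(cuts, function(ct) balanced_accuracy(scores, labels, ct),
               numeric(1))
  best <- which(ba >= max(ba) - 1e-12)
  threshold <- if (ties == "smallest") cuts[best[1]] else mean(cuts[best])
  list(threshold = threshold, balanced_accuracy = max(ba))
}

#' Optimal decision threshold by balanced accuracy
#'
#' Exhaustive sweep over midpoints of adjacent sorted scores; returns the cut
#' maximizing balanced accuracy, taking the smallest qualifying cut on ties.
#' Because the sweep is rank-based, any strictly monotone rescaling of the
#' scores yields the same partition of variants.
#'
#' @inheritParams balanced_accuracy
#' @return The optimal threshold (numeric scalar) with attribute
#'   `"balanced_accuracy"`.
#' @export
optimize_threshold <- function(scores, labels) {
  keep <- is.finite(scores) & !is.na(labels)
  res <- sweep_balanced_accuracy(scores[keep], labels[keep], ties = "smallest")
  structure(res$threshold, balanced_accuracy = res$balanced_accuracy)
}
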