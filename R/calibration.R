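#' Posterior pathogenicity probability from a likelihood ratio
#'
#' Bayes' rule on the odds scale: posterior odds = LR × prior odds. Strictly
#' increasing in both the likelihood ratio and the prior.
#'
#' @param prior Prior pathogenicity probability in (0, 1).
#' @param lr Positive likelihood ratio.
#' @return Posterior probability in (0, 1).
#' @examples
#' posterior_from_lr(0.1, 350) # 35 / 35.9
#' @export
posterior_from_lr <- function(prior, lr) {
  stopifnot(all(prior > 0 & prior < 1), all(lr > 0))
  lr * prior / (lr * prior + (1 - prior))
}

#' Likelihood-ratio cutoffs for graded evidence strengths
#'
#' Evidence strengths are geometric subdivisions of the very-strong
#' likelihood-ratio ceiling: supporting = ceiling^(1/8), moderate =
#' ceiling^(1/4), strong = ceiling^(1/2). Benign-side cutoffs are the
#' reciprocals.
#'
#' @param lr_ceiling Positive likelihood-ratio ceiling (default 350).
#' @return Tibble (`strength`, `pathogenic_lr`, `benign_lr`), strongest
#'   last.
#' @examples
#' strength_cutoffs(350) # 2.0802, 4.3272, 18.7083
#' @export
strength_cutoffs <- function(lr_ceiling = 350) {
  stopifnot(lr_ceiling > 1)
  path <- lr_ceiling^(c(1 / 8, 1 / 4, 1 / 2))
  tibble::tibble(
    strength = c("supporting", "moderate", "strong"),
    pathogenic_lr = path,
    benign_lr = 1 / path
  )
}

# Maps a (monotonized) local likelihood ratio to a PP3/BP4 evidence label.
evidence_from_lr <- function(lr, cutoffs) {
  dplyr::case_when(
    lr >= cutoffs$pathogenic_lr[3] ~ "PP3_strong",
    lr >= cutoffs$pathogenic_lr[2] ~ "PP3_moderate",
    lr >= cutoffs$pathogenic_lr[1] ~ "PP3_supporting",
    lr <= cutoffs$benign_lr[3] ~ "BP4_strong",
    lr <= cutoffs$benign_lr[2] ~ "BP4_moderate",
    lr <= cutoffs$benign_lr[1] ~ "BP4_supporting",
    TRUE ~ "none"
  )
}

#' Calibrate continuous scores to PP3/BP4 evidence strengths
#'
#' Local-likelihood-ratio calibration. The local positive fraction along the
#' score axis is estimated with a penalized logistic spline (smoothness by
#' REML) — the smoothed analogue of estimating local PPV in sliding score
#' windows, chosen because raw count windows are noisy exactly where the
#' evidence matters, in the score tails. The local empirical odds are
#' converted to likelihood ratios by dividing out the calibration set's
#' class balance (equivalently, reweighting to the target prior), capped at
#' the very-strong ceiling, and isotonic regression on the log scale
#' enforces that the likelihood ratio never decreases with score. Runs of
#' equal monotonized LR become score intervals carrying local PPV/NPV at the
#' target prior and the evidence strength implied by [strength_cutoffs()].
#' Being rank-smooth in the score, the evidence assignment is invariant to
#' strictly monotone transforms up to spline-placement effects.
#'
#' @param scores Numeric scores (higher = more pathogenic).
#' @param labels Binary labels (1 = pathogenic).
#' @param prior Target prior pathogenicity probability (default 0.1).
#' @param window_min Minimum calibration mass (default 100): at least
#'   `2 * window_min` variants are required, and the spline is given no more
#'   flexibility than one degree of freedom per `window_min` variants.
#' @param lr_ceiling Very-strong likelihood-ratio ceiling (default 350);
#'   also caps the fitted LR (and its reciprocal).
#' @return An `acmg_calibration` object: `prior`, `lr_ceiling`, `cutoffs`,
#'   and `intervals` (tibble `lower`, `upper`, `n`, `ppv`, `npv`, `lr`,
#'   `evidence` partitioning the real line).
#' @export
fit_calibration <- function(scores, labels, prior = 0.1, window_min = 100L,
                            lr_ceiling = 350) {
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n <- length(scores)
  if (n < 2 * window_min) {
    stop("need at least 2 * window_min calibration variants", call. = FALSE)
  }
  if (length(unique(labels)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  ord <- order(scores)
  s <- scores[ord]; y <- labels[ord]
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  n_unique <- length(unique(s))
  if (n_unique >= 4) {
    k <- max(4L, min(15L, as.integer(n %/% window_min) + 2L, n_unique - 1L))
    fit <- suppressWarnings(
      mgcv::gam(y ~ s(s, k = k), family = stats::binomial(),
                method = "REML")
    )
    p <- suppressWarnings(
      as.numeric(stats::predict(fit, type = "response"))
    )
  } else {
    p <- rep(mean(y), n)  # degenerate score support: no local information
  }
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  lr_raw <- (p / (1 - p)) * (n_neg / n_pos)
  lr_raw <- pmin(pmax(lr_raw, 1 / lr_ceiling), lr_ceiling)
  lr_fit <- exp(stats::isoreg(seq_len(n), log(lr_raw))$yf)

  runs <- rle(lr_fit)
  ends <- cumsum(runs$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  bounds <- c(-Inf, (s[utils::head(ends, -1)] + s[utils::head(ends, -1) + 1]) / 2,
              Inf)
  cutoffs <- strength_cutoffs(lr_ceiling)
  lr_run <- runs$values
  ppv <- posterior_from_lr(prior, lr_run)
  intervals <- tibble::tibble(
    lower = bounds[-length(bounds)],
    upper = bounds[-1],
    n = runs$lengths,
    ppv = ppv,
    npv = 1 - ppv,
    lr = lr_run,
    evidence = evidence_from_lr(lr_run, cutoffs)
  )
  structure(
    list(prior = prior, lr_ceiling = lr_ceiling, cutoffs = cutoffs,
         intervals = intervals, n = n),
    class = "acmg_calibration"
  )
}

#' @export
print.acmg_calibration <- function(x, ...) {
  cat(sprintf(
    "<acmg_calibration> n=%d  prior=%.2f  LR ceiling=%g  intervals=%d\n",
    x$n, x$prior, x$lr_ceiling, nrow(x$intervals)
  ))
  cat("evidence reached:",
      paste(unique(x$intervals$evidence), collapse = ", "), "\n")
  invisible(x)
}

#' Interpolated likelihood ratio at given scores
#'
#' Looks up the fitted interval containing each score (scores outside the
#' fitted range clamp to the nearest interval).
#'
#' @param table An `acmg_calibration`.
#' @param scores Numeric scores.
#' @return Numeric likelihood ratios.
#' @export
calibrated_lr <- function(table, scores) {
  idx <- findInterval(scores, table$intervals$lower,
                      rightmost.closed = FALSE)
  idx[idx < 1] <- 1
  table$intervals$lr[idx]
}

#' Assign PP3/BP4 evidence to scores
#'
#' @param scores Numeric scores.
#' @param table An `acmg_calibration` from [fit_calibration()].
#' @return Tibble (`score`, `lr`, `evidence`); `evidence` is `"none"` when
#'   the local likelihood ratio reaches no cutoff.
#' @export
assign_evidence <- function(scores, table) {
  lr <- calibrated_lr(table, scores)
  tibble::tibble(
    score = scores, lr = lr,
    evidence = evidence_from_lr(lr, table$cutoffs)
  )
}

#' Serialize a calibration table to TSV
#'
#' Writes the score intervals (bounds, PPV, NPV, likelihood ratio, evidence)
#' as TSV, with prior and ceiling in a JSON sidecar `<path>.json`.
#'
#' @param table An `acmg_calibration`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(table, path) {
  readr::write_tsv(table$intervals, path)
  jsonlite::write_json(
    list(prior = table$prior, lr_ceiling = table$lr_ceiling, n = table$n),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a calibration table written by [write_calibration()]
#'
#' @param path TSV path.
#' @return An `acmg_calibration`.
#' @export
read_calibration <- function(path) {
  intervals <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    list(prior = side$prior, lr_ceiling = side$lr_ceiling,
         cutoffs = strength_cutoffs(side$lr_ceiling),
         intervals = tibble::as_tibble(intervals), n = side$n),
    class = "acmg_calibration"
  )
}

# points per strength; benign criteria count negative
strength_points <- c(supporting = 1L, moderate = 2L, strong = 4L,
                     very_strong = 8L)

points_to_class <- function(points) {
  dplyr::case_when(
    points >= 10 ~ "P",
    points >= 6 ~ "LP",
    points >= 4 ~ "VUS_high",
    points >= 2 ~ "VUS_mid",
    points >= 0 ~ "VUS_low",
    points >= -6 ~ "LB",
    TRUE ~ "B"
  )
}

#' Combine ACMG criteria into a point-based class
#'
#' Point values follow the standard Bayesian points framework: supporting =
#' ±1, moderate = ±2, strong = ±4, very strong = +8 (pathogenic criteria
#' positive, benign negative). Bands: P ≥ 10, LP 6–9, VUS 0–5 (VUS_high 4–5,
#' VUS_mid 2–3, VUS_low 0–1), LB −6…−1, B ≤ −7. The combination is
#' permutation-invariant in the criteria; a profile carrying both PP3 and
#' BP4 is rejected.
#'
#' @param profile Tibble (`code`, `strength`) of triggered criteria, e.g.
#'   `tibble(code = c("PP3", "PM1"), strength = c("strong", "moderate"))`.
#'   Codes starting with `"P"` count pathogenic, `"B"` benign.
#' @return One-row tibble (`points`, `class`).
#' @export
combine_points <- function(profile) {
  if (nrow(profile) == 0) {
    return(tibble::tibble(points = 0L, class = "VUS_low"))
  }
  stopifnot(all(c("code", "strength") %in% names(profile)))
  if (all(c("PP3", "BP4") %in% profile$code)) {
    stop("a variant cannot carry both PP3 and BP4", call. = FALSE)
  }
  unknown <- setdiff(profile$strength, names(strength_points))
  if (length(unknown) > 0) {
    stop("unknown strength: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  sign <- ifelse(startsWith(profile$code, "B"), -1L, 1L)
  points <- sum(sign * strength_points[profile$strength])
  tibble::tibble(points = as.integer(points), class = points_to_class(points))
}

#' Classify many variants from an evidence table
#'
#' Vectorized [combine_points()] over a long evidence table.
#'
#' @param evidence Tibble (`variant_key`, `code`, `strength`).
#' @return Tibble (`variant_key`, `points`, `class`), one row per variant.
#' @export
acmg_classify <- function(evidence) {
  evidence |>
    dplyr::group_by(.data$variant_key) |>
    dplyr::group_modify(function(df, key) combine_points(df)) |>
    dplyr::ungroup()
}

#' Concordance and conclusiveness of ACMG classifications
#'
#' Concordance is the fraction of variants whose class agrees in sign with
#' the binary label: P/LP count pathogenic-concordant, B/LB
#' benign-concordant. Under `count_vus = "against"` (default) every VUS band
#' counts discordant; `"by_band"` lets VUS_high count pathogenic and VUS_low
#' benign, with VUS_mid always discordant. Conclusiveness = 1 − VUS_mid
#' fraction; sensitivity and specificity are computed over conclusive
#' (non-VUS_mid) calls.
#'
#' @param classes Character vector of classes (P/LP/VUS_high/VUS_mid/
#'   VUS_low/LB/B).
#' @param labels Binary labels (1 = pathogenic).
#' @param count_vus `"against"` or `"by_band"`.
#' @return One-row tibble (`sensitivity`, `specificity`, `concordance`,
#'   `conclusiveness`).
#' @export
classification_metrics <- function(classes, labels,
                                   count_vus = c("against", "by_band")) {
  count_vus <- match.arg(count_vus)
  if (length(classes) != length(labels)) {
    stop("classes and labels must have equal length", call. = FALSE)
  }
  path_classes <- c("P", "LP")
  benign_classes <- c("B", "LB")
  if (count_vus == "by_band") {
    path_classes <- c(path_classes, "VUS_high")
    benign_classes <- c(benign_classes, "VUS_low")
  }
  called_path <- classes %in% path_classes
  called_benign <- classes %in% benign_classes
  concordance <- mean((called_path & labels == 1) |
                        (called_benign & labels == 0))
  conclusive <- classes != "VUS_mid"
  sens <- mean(called_path[conclusive & labels == 1])
  spec <- mean(called_benign[conclusive & labels == 0])
  tibble::tibble(
    sensitivity = sens, specificity = spec,
    concordance = concordance,
    conclusiveness = 1 - mean(classes == "VUS_mid")
  )
}
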