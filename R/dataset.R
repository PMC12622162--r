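#' Calibrate a multiplexed assay study against clinical labels
#'
#' MAVE-style assay scores come with arbitrary scale and direction. This
#' calibrates one study against high-confidence clinical labels on the
#' overlapping variants: the orientation is auto-resolved (scores are flipped
#' when the rank AUC against the damaging class is below 0.5), separation is
#' tested with a one-sided Wilcoxon rank-sum test, and the study is accepted
#' only if the Bonferroni-corrected test passes and the labeled overlap is
#' large enough. Accepted studies get a binarization threshold maximizing
#' balanced accuracy on the overlap (ties broken toward the midpoint of tying
#' cuts). Being rank-based, the whole procedure is invariant to strictly
#' monotone transforms of the assay scores.
#'
#' @param study List with `study_id`, `gene`, and `scores` (named numeric
#'   vector, names = variant keys), optionally `orientation`.
#' @param clinical_labels Named binary vector (1 = pathogenic/damaging) keyed
#'   by variant key.
#' @param alpha Family-wise error target before Bonferroni division.
#' @param n_studies Number of studies tested (the Bonferroni denominator).
#' @param min_overlap Minimum labeled overlap required for calibration.
#' @return One-row tibble: `study_id`, `gene`, `n_overlap`, `auc`, `p_value`,
#'   `accepted`, `reason`, `binarization_threshold`, `orientation`, and
#'   `scores` (list column with the orientation-resolved scores, higher =
#'   more damaging).
#' @export
calibrate_assay_study <- function(study, clinical_labels, alpha = 0.05,
                                  n_studies = 1L, min_overlap = 10L) {
  stopifnot(alpha > 0, alpha < 1, n_studies >= 1)
  scores <- study$scores
  if (length(scores) < 1 || any(!is.finite(scores))) {
    stop("assay scores must be non-empty and finite", call. = FALSE)
  }
  keys <- intersect(names(scores), names(clinical_labels))
  base <- tibble::tibble(
    study_id = study$study_id, gene = study$gene,
    n_overlap = length(keys), auc = NA_real_, p_value = NA_real_,
    accepted = FALSE, reason = NA_character_,
    binarization_threshold = NA_real_, orientation = "unknown",
    scores = list(scores)
  )
  if (length(keys) < min_overlap) {
    base$reason <- "insufficient_overlap"
    return(base)
  }
  lab <- clinical_labels[keys]
  s <- scores[keys]
  a <- rank_auc(s, lab)
  orientation <- "higher_is_damaging"
  if (a < 0.5) {
    scores <- -scores
    s <- -s
    a <- 1 - a
    orientation <- "lower_is_damaging"
  }
  p <- stats::wilcox.test(s[lab == 1], s[lab == 0],
                          alternative = "greater", exact = FALSE)$p.value
  accepted <- p <= alpha / n_studies
  thr <- sweep_balanced_accuracy(s, lab, ties = "midpoint")$threshold
  base$auc <- a
  base$p_value <- p
  base$accepted <- accepted
  base$reason <- if (accepted) NA_character_ else "failed_performance_threshold"
  base$binarization_threshold <- thr
  base$orientation <- orientation
  base$scores <- list(scores)
  base
}

#' Sample weights for proxy-benign variants
#'
#' Population variants used as weak benign labels are down-weighted by their
#' allele frequency: rarer variants carry less confidence of benignity. The
#' weight is the log10 allele frequency, min-max normalized over the input
#' set, so the rarest variant gets weight 0 and the most common weight 1.
#' A degenerate (all-equal) input gets weight 1 throughout.
#'
#' @param allele_freqs Allele frequencies, all strictly inside (0, 1).
#'   Singletons are expected to have been excluded upstream.
#' @return Numeric weights in \[0, 1\], same order as the input.
#' @examples
#' compute_proxy_weights(c(1e-5, 1e-3, 1e-1)) # 0, 0.5, 1
#' @export
compute_proxy_weights <- function(allele_freqs) {
  if (length(allele_freqs) == 0) return(numeric(0))
  if (any(!is.finite(allele_freqs) | allele_freqs <= 0 | allele_freqs >= 1)) {
    stop("allele frequencies must lie strictly in (0, 1)", call. = FALSE)
  }
  lg <- log10(allele_freqs)
  rng <- range(lg)
  if (diff(rng) == 0) return(rep(1, length(lg)))
  (lg - rng[1]) / diff(rng)
}

#' Drop records whose effect is confounded by splicing disruption
#'
#' Variants predicted to disrupt splicing cannot be attributed a missense
#' mechanism, so they are removed from training data. Removal uses a strict
#' inequality (a score exactly at the cutoff is kept); records without a
#' splice score are retained.
#'
#' @param records Tibble with a `variant_key` column.
#' @param splice_scores Tibble (`variant_key`, `splice_score`) or a named
#'   numeric vector keyed by variant key.
#' @param cutoff Splice-disruption cutoff (default 0.2).
#' @return The filtered records tibble.
#' @export
exclude_splice_confounded <- function(records, splice_scores, cutoff = 0.2) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  if (is.data.frame(splice_scores)) {
    splice_scores <- stats::setNames(splice_scores$splice_score,
                                     splice_scores$variant_key)
  }
  sc <- splice_scores[records$variant_key]
  drop <- !is.na(sc) & sc > cutoff
  records[!drop, , drop = FALSE]
}

#' Balance classes within each gene
#'
#' Within every gene carrying both classes, the majority class is uniformly
#' down-sampled (seeded) to the minority count, so per-gene label composition
#' cannot be learned as a shortcut. Genes with a single class are dropped by
#' default, or kept capped under `"keep_capped"` (cap = the median per-class
#' size of the balanced two-class genes; all records if no such gene exists).
#' Output order is deterministic for a fixed seed: genes sorted, selected
#' records in original order.
#'
#' @param records Tibble with `variant_key`, `gene`, `label` columns.
#' @param seed Integer seed for the down-sampling draws.
#' @param single_class_policy `"drop"` or `"keep_capped"`.
#' @return A balanced tibble of the same columns.
#' @export
balance_per_gene <- function(records, seed = 1L,
                             single_class_policy = c("drop", "keep_capped")) {
  single_class_policy <- match.arg(single_class_policy)
  if (nrow(records) == 0) return(records)
  stopifnot(all(c("gene", "label") %in% names(records)))
  records <- records[order(records$gene), , drop = FALSE]
  withr::with_seed(seed, {
    pieces <- lapply(split(seq_len(nrow(records)), records$gene), function(idx) {
      lab <- records$label[idx]
      n1 <- sum(lab == 1); n0 <- sum(lab == 0)
      if (n1 == 0 || n0 == 0) return(list(idx = idx, single = TRUE))
      k <- min(n1, n0)
      keep <- c(
        sort(sample(idx[lab == 1], k)),
        sort(sample(idx[lab == 0], k))
      )
      list(idx = sort(keep), single = FALSE)
    })
    single <- purrr::map_lgl(pieces, "single")
    balanced_idx <- unlist(purrr::map(pieces[!single], "idx"), use.names = FALSE)
    if (single_class_policy == "keep_capped" && any(single)) {
      per_class <- purrr::map_int(pieces[!single], function(p) {
        length(p$idx) %/% 2L
      })
      cap <- if (length(per_class) > 0) {
        max(1L, as.integer(stats::median(per_class)))
      } else NA_integer_
      capped_idx <- unlist(purrr::map(pieces[single], function(p) {
        if (is.na(cap) || length(p$idx) <= cap) p$idx
        else sort(sample(p$idx, cap))
      }), use.names = FALSE)
      balanced_idx <- c(balanced_idx, capped_idx)
    }
  })
  records[sort(balanced_idx), , drop = FALSE]
}

#' Build the functional training dataset
#'
#' Integrates the heterogeneous functional evidence sources into one balanced
#' labeled dataset: accepted assay studies are binarized at their calibrated
#' thresholds; curated, assay-derived, and text-mined labels are merged with
#' precedence `curated > mave > text_mined` (conflicts within one tier are
#' dropped; a higher tier overrides a lower one); proxy-benign population
#' variants are added only when their key appears in no labeled source, with
#' weights from [compute_proxy_weights()]; per-gene balancing is applied last.
#'
#' @param mave Tibble of calibrated studies ([calibrate_assay_study()] rows).
#' @param curated Tibble (`variant_key`, `gene`, `label`) of curated records.
#' @param text_mined Same shape as `curated`.
#' @param proxy_benign Tibble (`variant_key`, `gene`, `af`) of population
#'   variants (singletons excluded upstream).
#' @param gene_map Optional named vector mapping variant keys to genes for
#'   assay variants lacking one.
#' @param seed Seed for the balancing draws.
#' @param single_class_policy Passed to [balance_per_gene()].
#' @return Labeled dataset tibble: `variant_key`, `gene`, `label`, `source`,
#'   `sample_weight`.
#' @export
build_functional_dataset <- function(mave = NULL, curated = NULL,
                                     text_mined = NULL, proxy_benign = NULL,
                                     gene_map = NULL, seed = 1L,
                                     single_class_policy = "drop") {
  empty <- tibble::tibble(
    variant_key = character(0), gene = character(0), label = integer(0),
    source = character(0), sample_weight = numeric(0)
  )
  tiers <- list()
  if (!is.null(curated) && nrow(curated) > 0) {
    tiers$curated <- dplyr::mutate(
      curated[, c("variant_key", "gene", "label")], source = "curated"
    )
  }
  if (!is.null(mave) && nrow(mave) > 0) {
    acc <- mave[mave$accepted, , drop = FALSE]
    if (nrow(acc) > 0) {
      tiers$mave <- dplyr::bind_rows(purrr::pmap(
        acc[, c("gene", "binarization_threshold", "scores")],
        function(gene, binarization_threshold, scores) {
          tibble::tibble(
            variant_key = names(scores),
            gene = if (!is.null(gene_map)) {
              dplyr::coalesce(unname(gene_map[names(scores)]), gene)
            } else gene,
            label = as.integer(scores >= binarization_threshold),
            source = "mave"
          )
        }
      ))
    }
  }
  if (!is.null(text_mined) && nrow(text_mined) > 0) {
    tiers$text_mined <- dplyr::mutate(
      text_mined[, c("variant_key", "gene", "label")], source = "text_mined"
    )
  }
  merged <- empty[, c("variant_key", "gene", "label", "source")]
  for (tier in c("curated", "mave", "text_mined")) {
    tb <- tiers[[tier]]
    if (is.null(tb)) next
    # within-tier conflicts: same key, both labels -> drop entirely
    conflict <- unique(tb$variant_key[duplicated(tb[, c("variant_key")]) |
                                        duplicated(tb[, c("variant_key")],
                                                   fromLast = TRUE)])
    conflict <- intersect(
      conflict,
      tb |>
        dplyr::distinct(.data$variant_key, .data$label) |>
        dplyr::count(.data$variant_key) |>
        dplyr::filter(.data$n > 1) |>
        dplyr::pull("variant_key")
    )
    tb <- dplyr::distinct(
      tb[!tb$variant_key %in% conflict, , drop = FALSE],
      .data$variant_key, .keep_all = TRUE
    )
    tb <- tb[!tb$variant_key %in% merged$variant_key, , drop = FALSE]
    merged <- dplyr::bind_rows(merged, tb)
  }
  merged$sample_weight <- 1.0
  if (!is.null(proxy_benign) && nrow(proxy_benign) > 0) {
    pb <- proxy_benign[!proxy_benign$variant_key %in% merged$variant_key, ,
                       drop = FALSE]
    if (nrow(pb) > 0) {
      pb <- tibble::tibble(
        variant_key = pb$variant_key, gene = pb$gene, label = 0L,
        source = "proxy_benign",
        sample_weight = compute_proxy_weights(pb$af)
      )
      merged <- dplyr::bind_rows(merged, pb)
    }
  }
  if (nrow(merged) == 0) return(empty)
  balance_per_gene(merged, seed = seed,
                   single_class_policy = single_class_policy)
}

#' Build the clinical training dataset
#'
#' Keeps ClinVar-style records with review status of at least two stars and a
#' conclusive classification (pathogenic, likely pathogenic, benign, likely
#' benign — ambiguous, conflicting and VUS annotations are excluded),
#' collapses to a binary label, removes splice-confounded variants
#' (score > `splice_cutoff`), and balances per gene.
#'
#' @param clinvar_records Tibble with `variant_key`, `gene`, `stars` (0–4)
#'   and `class` (character) columns.
#' @param splice_scores Passed to [exclude_splice_confounded()]; `NULL`
#'   skips the filter.
#' @param splice_cutoff Splice-disruption cutoff (default 0.2).
#' @param min_stars Minimum review stars (default 2).
#' @param seed Seed for balancing.
#' @param single_class_policy Passed to [balance_per_gene()].
#' @return Labeled dataset tibble: `variant_key`, `gene`, `label`, `source`,
#'   `sample_weight` (always 1).
#' @export
build_clinical_dataset <- function(clinvar_records, splice_scores = NULL,
                                   splice_cutoff = 0.2, min_stars = 2L,
                                   seed = 1L, single_class_policy = "drop") {
  stopifnot(all(c("variant_key", "gene", "stars", "class") %in%
                  names(clinvar_records)))
  cls <- tolower(trimws(clinvar_records$class))
  label_map <- c(
    "pathogenic" = 1L, "likely pathogenic" = 1L,
    "benign" = 0L, "likely benign" = 0L
  )
  known <- cls %in% names(label_map)
  n_skipped <- sum(!known)
  if (n_skipped > 0) {
    message(n_skipped,
            " record(s) skipped: ambiguous, conflicting or VUS class")
  }
  rec <- clinvar_records[known & clinvar_records$stars >= min_stars, ,
                         drop = FALSE]
  rec <- tibble::tibble(
    variant_key = rec$variant_key, gene = rec$gene,
    label = unname(label_map[tolower(trimws(rec$class))]),
    source = "clinvar", sample_weight = 1.0
  )
  if (!is.null(splice_scores)) {
    rec <- exclude_splice_confounded(rec, splice_scores,
                                     cutoff = splice_cutoff)
  }
  balance_per_gene(rec, seed = seed,
                   single_class_policy = single_class_policy)
}
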