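#' Cumulative allele frequency of a variant set
#'
#' Sum of the per-variant allele frequencies of a gene's qualifying variants,
#' clamped at 1 (a clamp triggers a warning: summed independent frequencies
#' can exceed 1 in principle).
#'
#' @param afs Allele frequencies, each in \[0, 1\].
#' @return CAF in \[0, 1\].
#' @export
cumulative_allele_frequency <- function(afs) {
  if (any(afs < 0 | afs > 1, na.rm = TRUE)) {
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  }
  caf <- sum(afs, na.rm = TRUE)
  if (caf > 1) {
    warning("cumulative allele frequency clamped from ",
            format(caf, digits = 4), " to 1", call. = FALSE)
    caf <- 1
  }
  caf
}

#' Carrier frequency under Hardy–Weinberg equilibrium
#'
#' Probability of carrying at least one qualifying allele. Autosomal modes
#' (AD/AR): 1 − (1 − CAF)². X-linked modes assume a 50/50 sex ratio: males
#' carry with probability CAF (hemizygous), females with 1 − (1 − CAF)².
#'
#' @param caf Cumulative allele frequency in \[0, 1\] (vectorized).
#' @param inheritance `"AD"`, `"AR"`, `"XLR"` or `"XLD"` (vectorized).
#' @return Carrier frequency in \[0, 1\].
#' @export
carrier_frequency <- function(caf, inheritance) {
  stopifnot(all(caf >= 0 & caf <= 1))
  check_inheritance(inheritance)
  n <- max(length(caf), length(inheritance))
  caf <- rep_len(caf, n)
  inheritance <- rep_len(inheritance, n)
  auto <- 1 - (1 - caf)^2
  ifelse(inheritance %in% c("AD", "AR"), auto,
         0.5 * caf + 0.5 * auto)
}

#' Genetic prevalence under Hardy–Weinberg equilibrium
#'
#' Frequency of affected genotypes for the inheritance mode:
#' * AR: CAF² (homozygous/compound heterozygous),
#' * AD: 1 − (1 − CAF)² (any carrier),
#' * XLR: CAF·(CAF + 1)/2 (affected hemizygous males plus homozygous
#'   females, pooled 50/50),
#' * XLD: (1 − CAF)·CAF + CAF·(CAF + 1)/2 (heterozygous females add to the
#'   XLR genotypes).
#'
#' @inheritParams carrier_frequency
#' @return Genetic prevalence in \[0, 1\].
#' @export
genetic_prevalence <- function(caf, inheritance) {
  stopifnot(all(caf >= 0 & caf <= 1))
  check_inheritance(inheritance)
  n <- max(length(caf), length(inheritance))
  caf <- rep_len(caf, n)
  inheritance <- rep_len(inheritance, n)
  dplyr::case_when(
    inheritance == "AR" ~ caf^2,
    inheritance == "AD" ~ 1 - (1 - caf)^2,
    inheritance == "XLR" ~ caf * (caf + 1) / 2,
    inheritance == "XLD" ~ (1 - caf) * caf + caf * (caf + 1) / 2
  )
}

check_inheritance <- function(inheritance) {
  unknown <- setdiff(unique(inheritance), c("AD", "AR", "XLR", "XLD"))
  if (length(unknown) > 0) {
    stop("unknown inheritance mode: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  invisible(inheritance)
}

#' Bayesian penetrance estimate
#'
#' P(D|C) = P(D)·P(C|D)/P(C): disease probability given carriage, from the
#' phenotype prevalence, the carrier frequency among cases, and the carrier
#' frequency in the population. Noisy inputs can push the ratio above 1; it
#' is then clamped with a warning.
#'
#' @param prevalence P(D), in (0, 1).
#' @param carrier_in_cases P(C|D), in (0, 1\].
#' @param carrier_in_population P(C), in (0, 1\].
#' @return Penetrance in \[0, 1\] (vectorized).
#' @examples
#' penetrance(0.01, 0.05, 0.001) # 0.5
#' @export
penetrance <- function(prevalence, carrier_in_cases, carrier_in_population) {
  if (any(carrier_in_population == 0)) {
    stop("population carrier frequency must be positive", call. = FALSE)
  }
  stopifnot(
    all(prevalence > 0 & prevalence < 1),
    all(carrier_in_cases > 0 & carrier_in_cases <= 1),
    all(carrier_in_population > 0 & carrier_in_population <= 1)
  )
  p <- prevalence * carrier_in_cases / carrier_in_population
  if (any(p > 1)) {
    warning("penetrance clamped to 1 for ", sum(p > 1), " input(s)",
            call. = FALSE)
    p <- pmin(p, 1)
  }
  p
}

#' Cohort-level carriage summary
#'
#' Under independence across genes, the probability that an individual
#' carries a qualifying variant in at least one gene is
#' 1 − Π(1 − CrF_g); the expected number of affected genotypes is Σ GP_g.
#'
#' @param records Tibble with `crf` and `gp` columns (one row per gene).
#' @return One-row tibble (`p_any_carrier`, `expected_genotypes`).
#' @export
cohort_carriage <- function(records) {
  if (nrow(records) == 0) {
    return(tibble::tibble(p_any_carrier = 0, expected_genotypes = 0))
  }
  tibble::tibble(
    p_any_carrier = 1 - prod(1 - records$crf),
    expected_genotypes = sum(records$gp)
  )
}

#' Rank a gene's genetic prevalence among comparators
#'
#' Dense rank by descending GP among the target and its comparator genes;
#' ties share the smaller (better) rank.
#'
#' @param target_gene_gp GP of the gene of interest.
#' @param comparator_gps GP values of established genes for the phenotype.
#' @return Integer rank (1 = largest GP).
#' @export
rank_gp <- function(target_gene_gp, comparator_gps) {
  stopifnot(length(comparator_gps) >= 1)
  vals <- sort(unique(c(target_gene_gp, comparator_gps)), decreasing = TRUE)
  match(target_gene_gp, vals)
}

#' Per-gene epidemiology records
#'
#' Convenience builder: groups a classified allele-frequency table by gene
#' (and ancestry when present), sums allele frequencies of qualifying
#' variants into the CAF, and derives carrier frequency and genetic
#' prevalence from the gene's inheritance mode.
#'
#' @param af_table Tibble (`variant_key`, `gene`, `af`, optional
#'   `ancestry`), already restricted to qualifying variants.
#' @param inheritance Tibble (`gene`, `inheritance`).
#' @return Tibble (`gene`, `ancestry?`, `inheritance`, `caf`, `crf`, `gp`).
#' @export
gene_epi_records <- function(af_table, inheritance) {
  grp <- intersect(c("gene", "ancestry"), names(af_table))
  out <- af_table |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(caf = cumulative_allele_frequency(.data$af),
                     .groups = "drop") |>
    dplyr::inner_join(inheritance, by = "gene")
  out$crf <- carrier_frequency(out$caf, out$inheritance)
  out$gp <- genetic_prevalence(out$caf, out$inheritance)
  out
}

mask_definitions <- function(score_cutoff = 0.631, splice_cutoff = 0.2) {
  vus_any <- c("P", "LP", "VUS_high", "VUS_mid", "VUS_low")
  list(
    list(id = 1L, name = "P",
         rule = function(d) d$acmg_class %in% "P"),
    list(id = 2L, name = "P+LP",
         rule = function(d) d$acmg_class %in% c("P", "LP")),
    list(id = 3L, name = "P+LP+VUS-H",
         rule = function(d) d$acmg_class %in% c("P", "LP", "VUS_high")),
    list(id = 4L, name = "P+LP+VUS-H+FuncD",
         rule = function(d) d$acmg_class %in% c("P", "LP", "VUS_high") |
           (d$consequence == "missense" & d$acmg_class %in% vus_any &
              !is.na(d$score) & d$score > score_cutoff)),
    list(id = 5L, name = "FuncD",
         rule = function(d) d$consequence == "missense" &
           d$acmg_class %in% vus_any & !is.na(d$score) &
           d$score > score_cutoff),
    list(id = 6L, name = "PVS1-VS",
         rule = function(d) d$pvs1 %in% "very_strong"),
    list(id = 7L, name = "PVS1-S",
         rule = function(d) d$pvs1 %in% "strong"),
    list(id = 8L, name = "PVS1-M",
         rule = function(d) d$pvs1 %in% "moderate"),
    list(id = 9L, name = "PVS1-P",
         rule = function(d) d$pvs1 %in% "supporting"),
    list(id = 10L, name = "PVS1-VS+S",
         rule = function(d) d$pvs1 %in% c("very_strong", "strong")),
    list(id = 11L, name = "PVS1-VS+S+M",
         rule = function(d) d$pvs1 %in% c("very_strong", "strong",
                                          "moderate")),
    list(id = 12L, name = "PVS1-VS+S+M+P",
         rule = function(d) d$pvs1 %in% c("very_strong", "strong",
                                          "moderate", "supporting")),
    list(id = 13L, name = "synonymous",
         rule = function(d) d$consequence == "synonymous" &
           !is.na(d$splice_score) & d$splice_score < splice_cutoff)
  )
}

#' Build rare-variant association masks
#'
#' Materializes the 13 named variant masks used for gene-level burden
#' aggregation — ACMG-classified strata (P; P+LP; P+LP+VUS-H; plus
#' predictor-damaging missense), the predictor-damaging mask itself
#' (missense, any class, score > `score_cutoff`), predicted loss-of-function
#' strata by PVS1 strength and their unions, and non-splice-altering
#' synonymous variants — each crossed with four allele-frequency strata
#' (AF ≤ 0.5, ≤ 0.1, ≤ 0.01, and singletons AC = 1).
#'
#' @param classified Tibble with columns `variant_key`, `consequence`
#'   (`"missense"`, `"synonymous"`, ...), `acmg_class`, `pvs1` (strength or
#'   `NA`), `score`, `af`, `ac`, `splice_score`.
#' @param score_cutoff Predictor-damaging score cutoff (default 0.631).
#' @param splice_cutoff Synonymous splice-safety cutoff (default 0.2).
#' @return Long tibble (`mask_id`, `mask_name`, `af_threshold`,
#'   `variant_key`), one row per qualifying variant per mask–stratum.
#' @export
build_masks <- function(classified, score_cutoff = 0.631,
                        splice_cutoff = 0.2) {
  required <- c("variant_key", "consequence", "acmg_class", "pvs1",
                "score", "af", "ac", "splice_score")
  missing_cols <- setdiff(required, names(classified))
  if (length(missing_cols) > 0) {
    stop("classified table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  af_strata <- list(
    "0.5" = function(d) !is.na(d$af) & d$af <= 0.5,
    "0.1" = function(d) !is.na(d$af) & d$af <= 0.1,
    "0.01" = function(d) !is.na(d$af) & d$af <= 0.01,
    "singleton" = function(d) !is.na(d$ac) & d$ac == 1
  )
  defs <- mask_definitions(score_cutoff, splice_cutoff)
  dplyr::bind_rows(purrr::map(defs, function(def) {
    in_class <- def$rule(classified)
    dplyr::bind_rows(purrr::imap(af_strata, function(af_rule, af_name) {
      keep <- in_class & af_rule(classified)
      tibble::tibble(
        mask_id = def$id, mask_name = def$name, af_threshold = af_name,
        variant_key = classified$variant_key[keep]
      )
    }))
  }))
}
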