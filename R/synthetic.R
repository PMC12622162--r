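#' Configuration for the synthetic study generator
#'
#' Fixes the conditions every synthetic fixture is drawn under. Defaults
#' describe the reference synthetic study: 20 genes x 100 variants (2,000
#' variants), balanced labels, 25 features across the seven catalog
#' categories of which 5 are informative with a 2-sd class-mean shift,
#' 5% completely-at-random missingness plus two class-biased features, and
#' log-uniform allele frequencies between 1e-6 and 1e-2.
#'
#' Every draw is governed by `seed`; each generator operation derives its own
#' sub-stream as `seed + offset` (variants +1, features +2, assays +3,
#' population +4), so composite fixtures are reproducible module by module.
#'
#' @param n_genes Number of genes.
#' @param variants_per_gene Variants simulated per gene.
#' @param p_damaging Per-variant probability of a damaging label.
#' @param n_features Named integer vector of feature counts per category
#'   (names drawn from the feature catalog categories).
#' @param n_informative Number of features carrying class signal.
#' @param shift Class-mean shift of informative features, in sd units.
#' @param mcar_rate Missing-completely-at-random rate applied to all
#'   features.
#' @param n_biased Number of noise features given class-biased missingness.
#' @param biased_rates Missingness rates (damaging class, neutral class) for
#'   biased features.
#' @param af_bounds Log-uniform allele-frequency bounds.
#' @param singleton_rate Fraction of population variants forced to allele
#'   count 1.
#' @param an Population allele number used to convert AF to allele counts.
#' @param seed Integer master seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 20L, variants_per_gene = 100L,
                       p_damaging = 0.5,
                       n_features = c(vep_score = 6L, conservation = 4L,
                                      structural = 3L,
                                      residue_constraint = 2L,
                                      substitution_matrix = 2L, plm = 4L,
                                      gene_level = 4L),
                       n_informative = 5L, shift = 2,
                       mcar_rate = 0.05, n_biased = 2L,
                       biased_rates = c(0.4, 0.05),
                       af_bounds = c(1e-6, 1e-2), singleton_rate = 0.1,
                       an = 1e5, seed = 1L) {
  stopifnot(n_genes >= 0, variants_per_gene >= 0, shift >= 0,
            all(n_features >= 0), n_informative <= sum(n_features),
            mcar_rate >= 0, mcar_rate < 1)
  structure(
    list(n_genes = n_genes, variants_per_gene = variants_per_gene,
         p_damaging = p_damaging, n_features = n_features,
         n_informative = n_informative, shift = shift,
         mcar_rate = mcar_rate, n_biased = n_biased,
         biased_rates = biased_rates, af_bounds = af_bounds,
         singleton_rate = singleton_rate, an = an, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a labeled variant dataset
#'
#' Genes x variants with Bernoulli(`p_damaging`) labels; positions are
#' unique, chromosomes cycle over the autosomes, and alleles are random
#' distinct bases. The label column is the ground-truth effect indicator.
#'
#' @param cfg A [sim_config()].
#' @return Tibble (`variant_key`, `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `label`, `source`, `sample_weight`).
#' @export
simulate_labeled_variants <- function(cfg) {
  n <- cfg$n_genes * cfg$variants_per_gene
  if (n == 0) {
    return(tibble::tibble(
      variant_key = character(0), chrom = character(0), pos = integer(0),
      ref = character(0), alt = character(0), gene = character(0),
      label = integer(0), source = character(0), sample_weight = numeric(0)
    ))
  }
  bases <- c("A", "C", "G", "T")
  withr::with_seed(cfg$seed + 1L, {
    gene <- rep(sprintf("G%03d", seq_len(cfg$n_genes)),
                each = cfg$variants_per_gene)
    chrom <- as.character(rep_len(1:22, cfg$n_genes))[
      rep(seq_len(cfg$n_genes), each = cfg$variants_per_gene)]
    pos <- rep(seq_len(cfg$n_genes) * 10000L, each = cfg$variants_per_gene) +
      rep(seq_len(cfg$variants_per_gene), cfg$n_genes)
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    label <- stats::rbinom(n, 1, cfg$p_damaging)
  })
  tibble::tibble(
    variant_key = variant_key(chrom, pos, ref, unname(alt)),
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = unname(alt),
    gene = gene, label = as.integer(label), source = "synthetic",
    sample_weight = 1
  )
}

# Feature names per category, catalog order; vep features carry tool ids.
synthetic_catalog <- function(cfg) {
  cats <- names(cfg$n_features)
  meta <- dplyr::bind_rows(purrr::map(cats, function(cat) {
    k <- cfg$n_features[[cat]]
    if (k == 0) return(NULL)
    tibble::tibble(
      feature = sprintf("%s_%02d", cat, seq_len(k)),
      category = cat,
      clinical_trained = if (cat == "vep_score") {
        seq_len(k) <= ceiling(k / 2)  # first half clinical-trained
      } else FALSE,
      tool_id = if (cat == "vep_score") {
        sprintf("tool_%s_%02d", cat, seq_len(k))
      } else NA_character_
    )
  }))
  meta
}

#' Simulate a feature matrix with known informative features
#'
#' Informative features are drawn N(label x shift, 1), noise features
#' N(0, 1). Informative features are assigned to non-predictor categories
#' first so every training regime retains signal. MCAR missingness applies
#' everywhere; the designated biased features go missing at class-dependent
#' rates (so [flag_biased_missingness()] has a ground truth to find).
#'
#' @param dataset Labeled dataset from [simulate_labeled_variants()].
#' @param cfg A [sim_config()].
#' @return List: `features` (wide tibble), `meta` (feature catalog with
#'   `informative` column), `informative` (character vector of truly
#'   informative feature names).
#' @export
simulate_feature_matrix <- function(dataset, cfg) {
  if (nrow(dataset) == 0) stop("dataset is empty", call. = FALSE)
  meta <- synthetic_catalog(cfg)
  if (cfg$n_informative > nrow(meta)) {
    stop("n_informative exceeds the number of features", call. = FALSE)
  }
  # non-predictor categories first, so CTE/SP regimes keep signal
  pref <- order(meta$category == "vep_score")
  informative <- meta$feature[pref][seq_len(cfg$n_informative)]
  noise_feats <- setdiff(meta$feature, informative)
  biased <- utils::head(noise_feats, cfg$n_biased)
  n <- nrow(dataset)
  withr::with_seed(cfg$seed + 2L, {
    cols <- purrr::map(meta$feature, function(f) {
      x <- stats::rnorm(n) +
        if (f %in% informative) dataset$label * cfg$shift else 0
      drop <- stats::runif(n) < cfg$mcar_rate
      if (f %in% biased) {
        rate <- ifelse(dataset$label == 1, cfg$biased_rates[1],
                       cfg$biased_rates[2])
        drop <- drop | stats::runif(n) < rate
      }
      x[drop] <- NA_real_
      x
    })
  })
  features <- tibble::as_tibble(stats::setNames(cols, meta$feature))
  features <- dplyr::bind_cols(
    tibble::tibble(variant_key = dataset$variant_key), features
  )
  meta$informative <- meta$feature %in% informative
  list(features = features, meta = meta, informative = informative)
}

#' Simulate per-gene assay studies
#'
#' One study per gene: assay score = label x `effect` + Gaussian noise, with
#' a per-study coin flip deciding whether higher scores mean damaging or the
#' scale is inverted. `uninformative = TRUE` severs the score–label link, so
#' calibration should reject the study.
#'
#' @param dataset Labeled dataset restricted to the genes to simulate.
#' @param cfg A [sim_config()].
#' @param effect Mean score separation between classes.
#' @param noise_sd Assay noise standard deviation.
#' @param flip_prob Probability a study reports an inverted scale.
#' @param uninformative Generate label-independent scores.
#' @return List of studies: each `list(study_id, gene, scores, flipped)`
#'   with `scores` a named numeric vector keyed by variant key.
#' @export
simulate_assay_studies <- function(dataset, cfg, effect = 1, noise_sd = 0.3,
                                   flip_prob = 0.5, uninformative = FALSE) {
  genes <- unique(dataset$gene)
  withr::with_seed(cfg$seed + 3L, {
    purrr::map(genes, function(g) {
      d <- dataset[dataset$gene == g, , drop = FALSE]
      mu <- if (uninformative) 0 else d$label * effect
      scores <- stats::rnorm(nrow(d), mean = mu, sd = noise_sd)
      flipped <- stats::runif(1) < flip_prob
      if (flipped) scores <- -scores
      list(study_id = paste0("study_", g), gene = g,
           scores = stats::setNames(scores, d$variant_key),
           flipped = flipped)
    })
  })
}

#' Simulate population allele frequencies, inheritance modes, and a tool
#' registry
#'
#' Allele frequencies are log-uniform within `cfg$af_bounds`; a
#' `cfg$singleton_rate` fraction of variants is forced to allele count 1.
#' Inheritance modes are drawn per gene (AD/AR common, X-linked rare). The
#' registry fixture is a random acyclic component graph over the catalog's
#' predictor tools (edges only from later to earlier tools), each tool
#' training on a random subset of the dataset's variants.
#'
#' @param dataset Labeled dataset whose keys the AF table covers.
#' @param cfg A [sim_config()].
#' @param meta Optional feature catalog (aligns registry tools and
#'   `clinical_trained` flags with the catalog's predictor features).
#' @param training_fraction Fraction of dataset variants in each tool's
#'   training set.
#' @param edge_prob Probability of a component edge between two tools.
#' @return List: `af_table` (tibble `variant_key`, `gene`, `af`, `ac`,
#'   `an`, `ancestry`), `inheritance` (tibble `gene`, `inheritance`),
#'   `registry` (a `tool_registry`).
#' @export
simulate_population <- function(dataset, cfg, meta = NULL,
                                training_fraction = 0.1, edge_prob = 0.3) {
  if (is.null(meta)) meta <- synthetic_catalog(cfg)
  vep <- meta[meta$category == "vep_score", , drop = FALSE]
  n <- nrow(dataset)
  withr::with_seed(cfg$seed + 4L, {
    af <- 10^stats::runif(n, log10(cfg$af_bounds[1]),
                          log10(cfg$af_bounds[2]))
    singleton <- stats::runif(n) < cfg$singleton_rate
    ac <- pmax(2L, as.integer(round(af * cfg$an)))
    ac[singleton] <- 1L
    af[singleton] <- 1 / cfg$an
    genes <- unique(dataset$gene)
    inheritance <- tibble::tibble(
      gene = genes,
      inheritance = sample(c("AD", "AR", "XLR", "XLD"), length(genes),
                           replace = TRUE, prob = c(0.4, 0.4, 0.1, 0.1))
    )
    tools <- stats::setNames(purrr::map(seq_len(nrow(vep)), function(i) {
      comp <- if (i > 1) {
        vep$tool_id[which(stats::runif(i - 1) < edge_prob)]
      } else character(0)
      list(
        training_variants = as.list(sample(
          dataset$variant_key,
          max(1L, round(n * training_fraction))
        )),
        components = as.list(comp),
        clinical_trained = vep$clinical_trained[i],
        training_unknown = FALSE
      )
    }), vep$tool_id)
  })
  list(
    af_table = tibble::tibble(
      variant_key = dataset$variant_key, gene = dataset$gene,
      af = af, ac = ac, an = as.integer(cfg$an), ancestry = "ALL"
    ),
    inheritance = inheritance,
    registry = if (nrow(vep) > 0) as_tool_registry(tools) else
      as_tool_registry(list())
  )
}
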