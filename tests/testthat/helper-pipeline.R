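# Runs the full command-line pipeline on the small preset inside `root`.
# Returns md5 checksums of every produced file, for determinism comparisons.
run_small_pipeline <- function(root, seed = 1, trials = 2) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  fix <- file.path(root, "fix")
  run <- function(...) {
    status <- vep_cli(c(...))
    stopifnot(identical(status, 0L))
  }
  run("simulate", "--preset", "small", "--seed", seed, "--out", fix)
  run("build-dataset", "--functional", "--in", fix, "--seed", seed,
      "--out", file.path(root, "func.tsv"))
  run("build-dataset", "--clinical", "--in", fix, "--seed", seed,
      "--out", file.path(root, "clin.tsv"))
  run("mask-scores", "--matrix", file.path(fix, "features.tsv"),
      "--meta", file.path(fix, "feature_meta.tsv"),
      "--registry", file.path(fix, "registry.json"),
      "--out", file.path(root, "masked.tsv"))
  run("impute", "--matrix", file.path(root, "masked.tsv"),
      "--background", file.path(fix, "features.tsv"),
      "--dataset", file.path(fix, "dataset.tsv"),
      "--seed", seed, "--out", file.path(root, "imputed.tsv"))
  for (regime in c("CTI", "CTE", "SP")) {
    run("train", "--regime", regime,
        "--dataset", file.path(root, "func.tsv"),
        "--matrix", file.path(root, "imputed.tsv"),
        "--meta", file.path(fix, "feature_meta.tsv"),
        "--trials", trials, "--seed", seed,
        "--out", file.path(root, paste0("model_", regime)))
  }
  run("predict", "--model", file.path(root, "model_CTI"),
      "--matrix", file.path(root, "imputed.tsv"),
      "--out", file.path(root, "preds.tsv"))
  run("attribute", "--model", file.path(root, "model_CTI"),
      "--matrix", file.path(root, "imputed.tsv"),
      "--meta", file.path(fix, "feature_meta.tsv"),
      "--out", file.path(root, "attr.tsv"))
  run("calibrate", "--scores", file.path(root, "preds.tsv"),
      "--dataset", file.path(fix, "dataset.tsv"),
      "--window-min", 15, "--out", file.path(root, "calib.tsv"))

  # evidence profiles from the calibrated scores, then point-based classes
  tab <- read_calibration(file.path(root, "calib.tsv"))
  preds <- readr::read_tsv(file.path(root, "preds.tsv"),
                           show_col_types = FALSE)
  scored <- preds[!is.na(preds$score), ]
  ev <- assign_evidence(scored$score, tab)
  evidence <- tibble::tibble(
    variant_key = scored$variant_key,
    code = sub("_.*", "", ev$evidence),
    strength = sub("^[^_]+_", "", ev$evidence)
  )
  evidence <- evidence[evidence$code != "none", ]
  readr::write_tsv(evidence, file.path(root, "evidence.tsv"))
  run("classify", "--evidence", file.path(root, "evidence.tsv"),
      "--out", file.path(root, "classes.tsv"))

  classes <- readr::read_tsv(file.path(root, "classes.tsv"),
                             show_col_types = FALSE)
  pop <- readr::read_tsv(file.path(fix, "population.tsv"),
                         show_col_types = FALSE)
  clin <- readr::read_tsv(file.path(fix, "clinical.tsv"),
                          show_col_types = FALSE)
  classified <- preds |>
    dplyr::left_join(classes, by = "variant_key") |>
    dplyr::left_join(pop[, c("variant_key", "af", "ac")],
                     by = "variant_key") |>
    dplyr::left_join(clin[, c("variant_key", "splice_score")],
                     by = "variant_key") |>
    dplyr::mutate(
      consequence = ifelse(seq_along(.data$variant_key) %% 5 == 0,
                           "synonymous", "missense"),
      acmg_class = dplyr::coalesce(.data$class.y, "VUS_low"),
      pvs1 = NA_character_
    ) |>
    dplyr::select("variant_key", "consequence", "acmg_class", "pvs1",
                  "score", "af", "ac", "splice_score")
  readr::write_tsv(classified, file.path(root, "classified.tsv"))
  run("masks", "--classified", file.path(root, "classified.tsv"),
      "--out", file.path(root, "masks.tsv"))

  tools_tbl <- tibble::tibble(
    variant_key = preds$variant_key,
    cti = preds$score,
    inverse = -preds$score
  )
  readr::write_tsv(tools_tbl, file.path(root, "tools.tsv"))
  run("benchmark", "--tools", file.path(root, "tools.tsv"),
      "--assays", file.path(fix, "assays.tsv"),
      "--registry", file.path(fix, "registry.json"),
      "--out", file.path(root, "bench"))
  run("epi", "--af", file.path(fix, "population.tsv"),
      "--inheritance", file.path(fix, "inheritance.tsv"),
      "--out", file.path(root, "epi"))

  files <- sort(list.files(root, recursive = TRUE, full.names = TRUE))
  # run manifests record the invocation (absolute input paths), so they are
  # not comparable across working directories; data outputs are
  files <- files[basename(files) != "manifest.json"]
  sums <- tools::md5sum(files)
  names(sums) <- sub(paste0("^", root, "/?"), "", names(sums))
  sums
}
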