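#' Canonical variant keys
#'
#' Builds the canonical `chrom:pos:ref:alt` key used to join variants across
#' every table in the pipeline. Chromosome names are normalized by stripping a
#' leading `"chr"` so that keys merge safely across sources that disagree on
#' the prefix.
#'
#' @param chrom Chromosome name (character).
#' @param pos 1-based genomic position (integer-like).
#' @param ref,alt Reference and alternate allele strings.
#' @return Character vector of keys, one per variant.
#' @examples
#' variant_key(c("chr1", "2"), c(100, 200), c("A", "G"), c("T", "C"))
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  chrom <- sub("^chr", "", as.character(chrom))
  paste(chrom, as.integer(pos), as.character(ref), as.character(alt), sep = ":")
}

#' Validate a variant table
#'
#' Checks the invariants every variant table must satisfy: positions are
#' >= 1, ref differs from alt, and the canonical key is unique.
#'
#' @param variants A data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @return The input as a tibble with a `variant_key` column, invisibly
#'   unchanged otherwise.
#' @export
validate_variants <- function(variants) {
  variants <- tibble::as_tibble(variants)
  required <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols) > 0) {
    stop("variant table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_pos <- which(!is.finite(variants$pos) | variants$pos < 1)
  if (length(bad_pos) > 0) {
    stop("position must be ≥ 1 (row ", bad_pos[1], ")", call. = FALSE)
  }
  same <- which(variants$ref == variants$alt)
  if (length(same) > 0) {
    stop("ref must differ from alt (row ", same[1], ")", call. = FALSE)
  }
  key <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  dup <- key[duplicated(key)]
  if (length(dup) > 0) {
    stop("duplicate variant key(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  variants$variant_key <- key
  dplyr::relocate(variants, "variant_key")
}

#' Read a variant table from TSV or VCF
#'
#' TSV tables must carry a header with at least `chrom`, `pos`, `ref`, `alt`;
#' any additional columns (gene, protein change, numeric features) are kept,
#' with missing numeric entries preserved as `NA`. VCF input is parsed with
#' \pkg{vcfR}; multi-allelic rows are split one alternate allele per record.
#' Coordinates are 1-based and fully closed, as in VCF.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @return A tibble of variants with a canonical `variant_key` column.
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "tsv") {
    tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    if (!all(c("chrom", "pos", "ref", "alt") %in% names(tbl))) {
      stop("TSV header must include chrom, pos, ref, alt", call. = FALSE)
    }
    bad <- which(!is.finite(tbl$pos) | tbl$pos < 1)
    if (length(bad) > 0) {
      # +1 for the header line so the message points at the file line
      stop("position must be ≥ 1 (line ", bad[1] + 1L, ")", call. = FALSE)
    }
  } else {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- tibble::as_tibble(vcfR::getFIX(vcf))
    tbl <- tibble::tibble(
      chrom = fix$CHROM,
      pos = as.integer(fix$POS),
      ref = fix$REF,
      alt = fix$ALT
    )
    tbl <- tidyr::separate_rows(tbl, "alt", sep = ",")
  }
  validate_variants(tbl)
}

#' Write per-variant prediction scores and classes
#'
#' Writes scores/classes next to their variants, either as a TSV (round-trips
#' numeric values at full precision) or as minimal VCF 4.2 with `SCORE` and
#' `CLASS` INFO keys. Missing scores are written as `NA` in TSV and `.` in
#' VCF INFO, following ecosystem convention.
#'
#' @param variants Variant tibble (see [validate_variants()]).
#' @param scores Numeric vector of model scores, same length as `variants`.
#' @param classes Character vector of predicted classes, same length.
#' @param path Output path.
#' @param dialect `"tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(variants, scores, classes, path,
                              dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  variants <- validate_variants(variants)
  if (nrow(variants) != length(scores) || nrow(variants) != length(classes)) {
    stop("variants, scores and classes must have equal length", call. = FALSE)
  }
  if (dialect == "tsv") {
    out <- dplyr::mutate(
      variants[, c("variant_key", "chrom", "pos", "ref", "alt")],
      score = as.numeric(scores), class = as.character(classes)
    )
    readr::write_tsv(out, path)
  } else {
    info <- sprintf(
      "SCORE=%s;CLASS=%s",
      ifelse(is.na(scores), ".", format(scores, digits = 15, trim = TRUE)),
      ifelse(is.na(classes), ".", as.character(classes))
    )
    header <- c(
      "##fileformat=VCFv4.2",
      "##INFO=<ID=SCORE,Number=1,Type=Float,Description=\"Prediction score\">",
      "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Predicted class\">",
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
    )
    body <- if (nrow(variants) == 0) character(0) else sprintf(
      "%s\t%d\t.\t%s\t%s\t.\t.\t%s",
      variants$chrom, variants$pos, variants$ref, variants$alt, info
    )
    writeLines(c(header, body), path)
  }
  invisible(path)
}

#' Read a predictions file written by [write_predictions()]
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @return Tibble with `variant_key`, `score`, `class`.
#' @export
read_predictions <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    return(tibble::as_tibble(tbl))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(vcfR::getFIX(vcf, getINFO = TRUE))
  score_raw <- stringr::str_match(fix$INFO, "SCORE=([^;]+)")[, 2]
  class_raw <- stringr::str_match(fix$INFO, "CLASS=([^;]+)")[, 2]
  tibble::tibble(
    variant_key = variant_key(fix$CHROM, fix$POS, fix$REF, fix$ALT),
    chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
    score = suppressWarnings(as.numeric(ifelse(score_raw == ".", NA, score_raw))),
    class = ifelse(class_raw == ".", NA_character_, class_raw)
  )
}
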