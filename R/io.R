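#' Construct a PRS scoring file object
#'
#' A scoring file is a tibble of variants with the columns `variant_id`,
#' `chromosome`, `position` (1-based), `effect_allele`, `other_allele` and
#' `weight` (the per-effect-allele effect size beta). The score identifier
#' and trait label travel as attributes.
#'
#' @param variants Data frame with the six required columns.
#' @param score_id,trait_label Identifier and trait label of the score.
#' @return A tibble of class `score_file`.
#' @export
score_file <- function(variants, score_id = "PRS", trait_label = "") {
  req <- c("variant_id", "chromosome", "position",
           "effect_allele", "other_allele", "weight")
  missing_cols <- setdiff(req, names(variants))
  if (length(missing_cols)) {
    abort(sprintf("scoring file is missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  v <- tibble::as_tibble(variants)[req]
  v$chromosome <- as.character(v$chromosome)
  v$position <- as.integer(v$position)
  v$effect_allele <- toupper(v$effect_allele)
  v$other_allele <- toupper(v$other_allele)
  bad <- which(!(v$effect_allele %in% names(DNA_COMPLEMENT)) |
                 !(v$other_allele %in% names(DNA_COMPLEMENT)))
  if (length(bad)) {
    abort(sprintf("non-ACGT allele in scoring row(s): %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  same <- which(v$effect_allele == v$other_allele)
  if (length(same)) {
    abort(sprintf("effect and other allele identical in row(s): %s",
                  paste(head(same, 5), collapse = ", ")))
  }
  if (any(!is.finite(v$weight))) {
    abort("all weights must be finite")
  }
  dup <- unique(v$variant_id[duplicated(v$variant_id)])
  if (length(dup)) {
    abort(sprintf("duplicated variant_id in scoring file: %s",
                  paste(head(dup, 5), collapse = ", ")))
  }
  structure(v,
            score_id = score_id, trait_label = trait_label,
            class = c("score_file", class(v)))
}

#' Construct a genotype dosage panel
#'
#' Holds per-variant metadata and a variants-by-individuals dosage matrix.
#' `allele1` is the dosage-counted allele; every dosage must lie in
#' `[0, 2]`.
#'
#' @param variants Tibble with columns `variant_id`, `chromosome`,
#'   `position`, `allele1`, `allele2`, `info_score`.
#' @param dosages Numeric matrix, one row per variant, one column per
#'   individual.
#' @param sample_ids Character vector of individual identifiers.
#' @return A list of class `dosage_panel`.
#' @export
dosage_panel <- function(variants, dosages, sample_ids) {
  variants <- tibble::as_tibble(variants)
  req <- c("variant_id", "chromosome", "position", "allele1", "allele2",
           "info_score")
  missing_cols <- setdiff(req, names(variants))
  if (length(missing_cols)) {
    abort(sprintf("panel variant table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  dosages <- as.matrix(dosages)
  if (nrow(variants) != nrow(dosages) ||
      length(sample_ids) != ncol(dosages)) {
    abort("panel dimensions are inconsistent (variants x individuals)")
  }
  if (nrow(dosages) > 0 && ncol(dosages) > 0) {
    rng <- range(dosages)
    if (rng[1] < 0 || rng[2] > 2) {
      abort("dosages must lie in [0, 2]")
    }
  }
  dup <- unique(variants$variant_id[duplicated(variants$variant_id)])
  if (length(dup)) {
    abort(sprintf("duplicated variant_id in panel: %s",
                  paste(head(dup, 5), collapse = ", ")))
  }
  if (any(!is.finite(variants$info_score) | variants$info_score < 0 |
          variants$info_score > 1)) {
    abort("info_score must lie in [0, 1]")
  }
  dimnames(dosages) <- NULL
  structure(
    list(variants = variants, dosages = dosages,
         sample_ids = as.character(sample_ids)),
    class = "dosage_panel"
  )
}

#' @export
print.dosage_panel <- function(x, ...) {
  cat(sprintf("<dosage_panel> %d variants x %d individuals\n",
              nrow(x$variants), length(x$sample_ids)))
  print(head(x$variants), ...)
  invisible(x)
}

n_variants <- function(panel) nrow(panel$variants)

# Restrict a panel to a subset of individuals (used after sample QC).
subset_panel_samples <- function(panel, sample_ids) {
  keep <- match(sample_ids, panel$sample_ids)
  if (anyNA(keep)) abort("some sample_ids are not in the panel")
  dosage_panel(panel$variants, panel$dosages[, keep, drop = FALSE],
               panel$sample_ids[keep])
}

SCORE_FILE_HEADER <- c("rsID", "chr_name", "chr_position",
                       "effect_allele", "other_allele", "effect_weight")

read_tsv_quiet <- function(path, ...) {
  d <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE, ...)
  attr(d, "spec") <- NULL
  attr(d, "problems") <- NULL
  d
}

#' Read and write PGS-Catalog-style scoring files
#'
#' The layout is tab-separated with a header row `rsID`, `chr_name`,
#' `chr_position`, `effect_allele`, `other_allele`, `effect_weight`;
#' `#`-prefixed metadata lines are skipped on read and used to carry the
#' score id and trait label on write. Allele strings are upper-cased;
#' structural problems (missing columns, non-ACGT alleles, duplicate ids)
#' raise errors. CRLF line endings and trailing blank lines are tolerated.
#'
#' @param path File path.
#' @param score_id,trait_label Overrides for the metadata; by default taken
#'   from `#score_id=` / `#trait_label=` header lines when present.
#' @return `read_score_file()` returns a [score_file()];
#'   `write_score_file()` returns `path` invisibly.
#' @export
read_score_file <- function(path, score_id = NULL, trait_label = NULL) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  meta_lines <- grep("^#", readr::read_lines(path, n_max = 50), value = TRUE)
  meta <- function(key) {
    m <- grep(sprintf("^#%s=", key), meta_lines, value = TRUE)
    if (length(m)) sub(sprintf("^#%s=", key), "", m[1]) else NULL
  }
  d <- read_tsv_quiet(path, col_types = readr::cols(
    chr_name = readr::col_character(),
    chr_position = readr::col_integer(),
    effect_weight = readr::col_double(),
    .default = readr::col_character()
  ))
  missing_cols <- setdiff(SCORE_FILE_HEADER, names(d))
  if (length(missing_cols)) {
    abort(sprintf("scoring file %s is missing required column(s): %s",
                  path, paste(missing_cols, collapse = ", ")))
  }
  bad <- which(!(toupper(d$effect_allele) %in% names(DNA_COMPLEMENT)) |
                 !(toupper(d$other_allele) %in% names(DNA_COMPLEMENT)))
  if (length(bad)) {
    abort(sprintf("non-ACGT allele in %s at data line(s): %s",
                  path, paste(head(bad, 5), collapse = ", ")))
  }
  score_file(
    tibble::tibble(
      variant_id = d$rsID,
      chromosome = d$chr_name,
      position = d$chr_position,
      effect_allele = d$effect_allele,
      other_allele = d$other_allele,
      weight = d$effect_weight
    ),
    score_id = score_id %||% meta("score_id") %||% "PRS",
    trait_label = trait_label %||% meta("trait_label") %||% ""
  )
}

#' @rdname read_score_file
#' @param score A [score_file()] to write.
#' @export
write_score_file <- function(score, path) {
  stopifnot(inherits(score, "score_file"))
  header <- c(
    sprintf("#score_id=%s", attr(score, "score_id")),
    sprintf("#trait_label=%s", attr(score, "trait_label")),
    paste(SCORE_FILE_HEADER, collapse = "\t")
  )
  body <- sprintf("%s\t%s\t%d\t%s\t%s\t%s",
                  score$variant_id, score$chromosome, score$position,
                  score$effect_allele, score$other_allele,
                  format(score$weight, digits = 17, trim = TRUE,
                         scientific = FALSE))
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Read and write dosage panels
#'
#' Tab-separated layout: one row per variant with the metadata columns
#' `variant_id`, `chromosome`, `position`, `allele1`, `allele2`,
#' `info_score` followed by one dosage column per individual (column name =
#' sample id). Positions are 1-based. Dosages outside `[0, 2]` are rejected
#' with the offending variant and sample named.
#'
#' @param path File path.
#' @return `read_dosage_panel()` returns a [dosage_panel()];
#'   `write_dosage_panel()` returns `path` invisibly.
#' @export
read_dosage_panel <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  d <- read_tsv_quiet(path, col_types = readr::cols(
    variant_id = readr::col_character(),
    chromosome = readr::col_character(),
    position = readr::col_integer(),
    allele1 = readr::col_character(),
    allele2 = readr::col_character(),
    .default = readr::col_double()
  ))
  meta_cols <- c("variant_id", "chromosome", "position", "allele1",
                 "allele2", "info_score")
  missing_cols <- setdiff(meta_cols, names(d))
  if (length(missing_cols)) {
    abort(sprintf("dosage panel %s is missing column(s): %s",
                  path, paste(missing_cols, collapse = ", ")))
  }
  sample_ids <- setdiff(names(d), meta_cols)
  dos <- as.matrix(d[sample_ids])
  if (length(dos)) {
    bad <- which(dos < 0 | dos > 2, arr.ind = TRUE)
    if (nrow(bad)) {
      abort(sprintf(
        "dosage outside [0, 2] for variant %s, sample %s (value %g)",
        d$variant_id[bad[1, 1]], sample_ids[bad[1, 2]],
        dos[bad[1, 1], bad[1, 2]]
      ))
    }
  }
  dosage_panel(d[meta_cols], dos, sample_ids)
}

#' @rdname read_dosage_panel
#' @param panel A [dosage_panel()] to write.
#' @export
write_dosage_panel <- function(panel, path) {
  stopifnot(inherits(panel, "dosage_panel"))
  d <- panel$variants
  dos <- as.data.frame(panel$dosages)
  names(dos) <- panel$sample_ids
  readr::write_tsv(dplyr::bind_cols(d, dos), path, progress = FALSE)
  invisible(path)
}

COHORT_FLAGS <- c("sex_discordant", "related", "het_miss_outlier")

#' Read and write cohort tables
#'
#' Tab-separated per-individual table with columns `sample_id`, `outcome`
#' (0/1, must be non-missing), `age`, `sex` (`female`/`male`; may be
#' constant), `array`, `pc1`..`pc5` and the logical sample-QC flag columns
#' `sex_discordant`, `related`, `het_miss_outlier`.
#'
#' @param path File path.
#' @return `read_cohort()` returns a tibble; `write_cohort()` returns
#'   `path` invisibly.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  d <- read_tsv_quiet(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    outcome = readr::col_integer(),
    sex = readr::col_character(),
    array = readr::col_character(),
    sex_discordant = readr::col_logical(),
    related = readr::col_logical(),
    het_miss_outlier = readr::col_logical(),
    .default = readr::col_double()
  ))
  req <- c("sample_id", "outcome", "age", "sex", "array",
           paste0("pc", 1:5), COHORT_FLAGS)
  missing_cols <- setdiff(req, names(d))
  if (length(missing_cols)) {
    abort(sprintf("cohort table %s is missing column(s): %s",
                  path, paste(missing_cols, collapse = ", ")))
  }
  if (anyNA(d$outcome)) {
    abort(sprintf("missing outcome for sample(s): %s",
                  paste(head(d$sample_id[is.na(d$outcome)], 5),
                        collapse = ", ")))
  }
  if (!all(d$outcome %in% c(0L, 1L))) {
    abort("outcome must be 0/1")
  }
  d
}

#' @rdname read_cohort
#' @param cohort A cohort tibble to write.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_tsv(cohort, path, progress = FALSE)
  invisible(path)
}
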