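#' Variant quality-control thresholds
#'
#' The three standard filters applied to a scoring file against the target
#' panel: palindromic (A/T or C/G) variants are removed when their minor
#' allele frequency exceeds `ambiguous_maf_min` (their strand cannot be
#' resolved and near 50\% frequency neither can the allele assignment);
#' variants rarer than `rare_maf_max` are removed; and only variants with
#' imputation info score strictly greater than `info_min` are retained.
#'
#' @param ambiguous_maf_min MAF above which palindromic variants are
#'   dropped (default 0.49).
#' @param rare_maf_max MAF below which variants are dropped (default
#'   0.005).
#' @param info_min Imputation info score that must be strictly exceeded
#'   (default 0.4).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(ambiguous_maf_min = 0.49,
                          rare_maf_max = 0.005,
                          info_min = 0.4) {
  assert_scalar_number(ambiguous_maf_min, "ambiguous_maf_min", 0, 0.5)
  assert_scalar_number(rare_maf_max, "rare_maf_max", 0, 0.5, lo_open = TRUE)
  assert_scalar_number(info_min, "info_min", 0, 1)
  if (!(rare_maf_max < ambiguous_maf_min)) {
    abort("`rare_maf_max` must be below `ambiguous_maf_min`")
  }
  structure(list(ambiguous_maf_min = ambiguous_maf_min,
                 rare_maf_max = rare_maf_max, info_min = info_min),
            class = "qc_thresholds")
}

new_qc_report <- function(removed, n_input) {
  out <- tibble::tibble(rule = names(removed),
                        n_removed = as.integer(removed))
  structure(out,
            n_input = as.integer(n_input),
            n_retained = as.integer(n_input - sum(removed)),
            class = c("qc_report", class(out)))
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d input, %d retained\n",
              attr(x, "n_input"), attr(x, "n_retained")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  removed %-16s %d\n", paste0(x$rule[i], ":"),
                x$n_removed[i]))
  }
  invisible(x)
}

#' @export
tidy.qc_report <- function(x, ...) {
  tibble::tibble(rule = x$rule, n_removed = x$n_removed,
                 n_input = attr(x, "n_input"),
                 n_retained = attr(x, "n_retained"))
}

#' Minor allele frequency from panel dosages
#'
#' The counted-allele frequency is `mean(dosage) / 2`, folded to the minor
#' side: `min(f, 1 - f)`.
#'
#' @param panel A [dosage_panel()].
#' @param variant_id Optional variant id(s); default all panel variants.
#' @return Named numeric vector of MAFs in `[0, 0.5]`.
#' @export
compute_maf <- function(panel, variant_id = NULL) {
  stopifnot(inherits(panel, "dosage_panel"))
  if (ncol(panel$dosages) == 0) {
    abort("cannot compute MAF from a panel with no individuals")
  }
  idx <- if (is.null(variant_id)) {
    seq_len(nrow(panel$variants))
  } else {
    i <- match(variant_id, panel$variants$variant_id)
    if (anyNA(i)) {
      abort(sprintf("variant(s) not in panel: %s",
                    paste(variant_id[is.na(i)], collapse = ", ")))
    }
    i
  }
  f <- rowMeans(panel$dosages[idx, , drop = FALSE]) / 2
  setNames(pmin(f, 1 - f), panel$variants$variant_id[idx])
}

# Match scoring-file variants to panel rows: primary key variant_id,
# fallback chromosome:position for ids the panel does not carry.
match_to_panel <- function(score, panel) {
  i <- match(score$variant_id, panel$variants$variant_id)
  no_id <- which(is.na(i))
  if (length(no_id)) {
    key_score <- paste(score$chromosome[no_id], score$position[no_id],
                       sep = ":")
    key_panel <- paste(panel$variants$chromosome, panel$variants$position,
                       sep = ":")
    i[no_id] <- match(key_score, key_panel)
  }
  i
}

#' Apply variant QC to a scoring file against a target panel
#'
#' Removes, in order of precedence: variants absent from the panel
#' (`unmatched`); palindromic A/T or C/G variants whose target-panel MAF
#' exceeds `thresholds$ambiguous_maf_min` (`ambiguous`); variants with MAF
#' below `thresholds$rare_maf_max` (`rare`); and variants whose imputation
#' info score does not strictly exceed `thresholds$info_min` (`low_info`).
#' The relative order of retained variants is preserved and the operation
#' is idempotent. MAF is computed from the supplied panel, so run sample QC
#' first if frequencies should reflect the analysis population.
#'
#' @param score A [score_file()].
#' @param panel The target [dosage_panel()].
#' @param thresholds A [qc_thresholds()].
#' @return A list with the filtered `score` and a `report` (a `qc_report`).
#' @export
apply_variant_qc <- function(score, panel, thresholds = qc_thresholds()) {
  stopifnot(inherits(score, "score_file"), inherits(panel, "dosage_panel"))
  i <- match_to_panel(score, panel)
  unmatched <- is.na(i)
  maf <- rep(NA_real_, nrow(score))
  info <- rep(NA_real_, nrow(score))
  ok <- !unmatched
  if (any(ok)) {
    freq <- rowMeans(panel$dosages[i[ok], , drop = FALSE]) / 2
    maf[ok] <- pmin(freq, 1 - freq)
    info[ok] <- panel$variants$info_score[i[ok]]
  }
  palindromic <- is_palindromic(score$effect_allele, score$other_allele)
  ambiguous <- !unmatched & palindromic & maf > thresholds$ambiguous_maf_min
  rare <- !unmatched & !ambiguous & maf < thresholds$rare_maf_max
  low_info <- !unmatched & !ambiguous & !rare & info <= thresholds$info_min

  keep <- !(unmatched | ambiguous | rare | low_info)
  kept <- score_file(score[keep, ],
                     score_id = attr(score, "score_id"),
                     trait_label = attr(score, "trait_label"))
  report <- new_qc_report(
    c(unmatched = sum(unmatched), ambiguous = sum(ambiguous),
      rare = sum(rare), low_info = sum(low_info)),
    n_input = nrow(score)
  )
  list(score = kept, report = report)
}

#' Harmonize scoring-file alleles to the panel's dosage orientation
#'
#' Matches each scoring variant to the panel and works out how the
#' published effect allele relates to the panel's counted allele
#' (`allele1`):
#' \itemize{
#'   \item effect = `allele1`, other = `allele2`: aligned as is.
#'   \item effect = `allele2`, other = `allele1`: the dosage is
#'     complemented (`2 - d`) when the score is computed, keeping the
#'     published weight untouched; recorded as `flipped`. This is
#'     mathematically identical to negating the weight, up to an additive
#'     constant that standardization removes.
#'   \item strand flip (both alleles complement-match, in either order):
#'     resolved the same way, but only for non-palindromic pairs;
#'     recorded as `strand_flipped`.
#'   \item anything else: removed as `allele_mismatch`.
#' }
#'
#' @param score A [score_file()].
#' @param panel The target [dosage_panel()].
#' @return A list with `score` (the harmonized scoring tibble, carrying
#'   `panel_row` and `flip_dosage` columns consumed by [compute_prs()]) and
#'   `report` (a `qc_report`).
#' @export
harmonize_alleles <- function(score, panel) {
  stopifnot(inherits(score, "score_file"), inherits(panel, "dosage_panel"))
  i <- match_to_panel(score, panel)
  e <- score$effect_allele
  o <- score$other_allele
  a1 <- panel$variants$allele1[i]
  a2 <- panel$variants$allele2[i]
  pal <- is_palindromic(e, o)

  status <- rep("mismatch", nrow(score))
  status[is.na(i)] <- "unmatched"
  direct <- !is.na(i) & e == a1 & o == a2
  swapped <- !is.na(i) & e == a2 & o == a1
  strand <- !is.na(i) & !pal & complement_allele(e) == a1 &
    complement_allele(o) == a2
  strand_swapped <- !is.na(i) & !pal & complement_allele(e) == a2 &
    complement_allele(o) == a1
  status[direct] <- "direct"
  status[swapped] <- "swapped"
  status[strand] <- "strand"
  status[strand_swapped] <- "strand_swapped"

  keep <- status %in% c("direct", "swapped", "strand", "strand_swapped")
  out <- tibble::as_tibble(score)[keep, ]
  out$panel_row <- i[keep]
  out$flip_dosage <- status[keep] %in% c("swapped", "strand_swapped")
  out <- structure(out,
                   score_id = attr(score, "score_id"),
                   trait_label = attr(score, "trait_label"),
                   class = c("score_file", class(tibble::tibble())))
  report <- new_qc_report(
    c(unmatched = sum(status == "unmatched"),
      allele_mismatch = sum(status == "mismatch")),
    n_input = nrow(score)
  )
  attr(report, "n_flipped") <- sum(status %in% c("swapped", "strand_swapped"))
  attr(report, "n_strand_resolved") <-
    sum(status %in% c("strand", "strand_swapped"))
  list(score = out, report = report)
}

#' Apply sample QC to a cohort
#'
#' Removes every individual with any of the sample-QC flags set
#' (sex-discordant, related at 3rd degree or higher, heterozygosity or
#' missingness outlier). The flags are consumed, not derived: they come
#' from upstream genotyping QC.
#'
#' @param cohort A cohort tibble (see [read_cohort()]).
#' @return A list with the filtered `cohort` and a `report` whose rules are
#'   the individual flags (an individual with several flags counts under
#'   each, while the report's retained/removed totals count individuals
#'   once).
#' @export
apply_sample_qc <- function(cohort) {
  missing_cols <- setdiff(COHORT_FLAGS, names(cohort))
  if (length(missing_cols)) {
    abort(sprintf("cohort is missing QC flag column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  flagged <- Reduce(`|`, lapply(COHORT_FLAGS, function(f) cohort[[f]]))
  kept <- cohort[!flagged, ]
  per_flag <- vapply(COHORT_FLAGS, function(f) sum(cohort[[f]]), integer(1))
  report <- new_qc_report(c(any_flag = sum(flagged)),
                          n_input = nrow(cohort))
  attr(report, "per_flag") <- per_flag
  if (nrow(kept) == 0 && nrow(cohort) > 0) {
    warn("sample QC removed every individual")
  }
  list(cohort = kept, report = report)
}
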