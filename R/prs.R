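PRS_BIN_LEVELS <- c("<1", "1-20", "20-40", "40-60", "60-80", "80-99", ">=99")
PRS_BIN_BREAKS <- c(-Inf, 1, 20, 40, 60, 80, 99, Inf)

#' Compute per-individual polygenic risk scores
#'
#' The score of individual `j` is the weighted allele count
#' `sum_i beta_i * dosage_ij` over the retained variants, in scoring-file
#' order. The scoring file must already be harmonized against the panel
#' (see [harmonize_alleles()]); a plain `score_file` is harmonized on the
#' fly as a convenience. Entries flagged `flip_dosage` contribute
#' `beta * (2 - dosage)`, i.e. the dosage is complemented to the published
#' effect allele while the weight stays as published.
#'
#' @param score A harmonized [score_file()] (with `panel_row` and
#'   `flip_dosage` columns) or a plain one.
#' @param panel The [dosage_panel()] the harmonization refers to.
#' @return A tibble of class `prs_scores` with columns `sample_id` and
#'   `raw`; the number of variants used and the score id travel as
#'   attributes.
#' @export
compute_prs <- function(score, panel) {
  stopifnot(inherits(panel, "dosage_panel"))
  if (!all(c("panel_row", "flip_dosage") %in% names(score))) {
    score <- harmonize_alleles(score, panel)$score
  }
  if (nrow(score) == 0) {
    abort("no scoring variants left after QC/harmonization; score undefined")
  }
  d <- panel$dosages[score$panel_row, , drop = FALSE]
  if (any(score$flip_dosage)) {
    d[score$flip_dosage, ] <- 2 - d[score$flip_dosage, , drop = FALSE]
  }
  raw <- drop(crossprod(d, score$weight))
  out <- tibble::tibble(sample_id = panel$sample_ids, raw = as.numeric(raw))
  structure(out,
            n_variants_used = nrow(score),
            score_id = attr(score, "score_id") %||% "PRS",
            class = c("prs_scores", class(out)))
}

keep_prs_attrs <- function(new, old) {
  structure(new,
            n_variants_used = attr(old, "n_variants_used"),
            score_id = attr(old, "score_id"),
            class = unique(c("prs_scores", class(new))))
}

#' Standardize raw scores to mean 0, sd 1
#'
#' Uses the population standard deviation (divisor N) over the analysis
#' population, so the standardized column has exactly zero mean and unit
#' sd. Standardization is invariant to affine transforms of the raw score.
#'
#' @param scores A `prs_scores` tibble from [compute_prs()].
#' @return The same tibble with a `standardized` column added.
#' @export
standardize_prs <- function(scores) {
  x <- scores$raw
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (!is.finite(s) || s == 0) {
    abort("cannot standardize a constant score (zero variance)")
  }
  scores$standardized <- (x - m) / s
  keep_prs_attrs(scores, scores)
}

#' Percentile ranks on a 0-100 scale
#'
#' `100 * (rank - 0.5) / N` with average ranks on ties, so a sample of N
#' distinct values places exactly `N * k / 100` individuals at or above the
#' `100 - k` percentile, and an all-tied sample sits at percentile 50.
#'
#' @param x Numeric vector.
#' @return Numeric vector of percentiles in `[0, 100)`.
#' @export
percentile_rank <- function(x) {
  100 * (rank(x, ties.method = "average") - 0.5) / length(x)
}

#' Assign percentile ranks and seven risk bins
#'
#' Adds `percentile` (see [percentile_rank()]) and `bin`, an ordered factor
#' over the seven conventional risk categories `<1`, `1-20`, `20-40`,
#' `40-60`, `60-80`, `80-99`, `>=99` percent. Bins are half-open
#' `[lo, hi)`; the top bin is closed above, so `>=99` is the top 1\% of the
#' distribution. Ranking is performed in the full analysis population.
#'
#' @param scores A `prs_scores` tibble.
#' @param on Column to rank on (`"raw"` by default; any strictly monotone
#'   transform of it, such as `standardized`, gives identical bins).
#' @return The tibble with `percentile` and `bin` columns added.
#' @export
assign_bins <- function(scores, on = "raw") {
  x <- scores[[on]]
  if (is.null(x)) abort(sprintf("no `%s` column to rank on", on))
  scores$percentile <- percentile_rank(x)
  scores$bin <- cut(scores$percentile, breaks = PRS_BIN_BREAKS,
                    labels = PRS_BIN_LEVELS, right = FALSE,
                    ordered_result = TRUE)
  keep_prs_attrs(scores, scores)
}

#' One call from harmonized score to binned score vector
#'
#' Convenience wrapper: [compute_prs()], [standardize_prs()],
#' [assign_bins()].
#'
#' @inheritParams compute_prs
#' @return A `prs_scores` tibble with `raw`, `standardized`, `percentile`
#'   and `bin` columns.
#' @export
score_individuals <- function(score, panel) {
  assign_bins(standardize_prs(compute_prs(score, panel)))
}
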