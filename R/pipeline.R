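#' Render a cross-classification table as text
#'
#' Formats a [cross_classify()] result the way published reclassification
#' tables are laid out: one row per bin of the first score, one column per
#' bin of the second, each cell `n (row%, col%, cell%)` with percentages to
#' one decimal. Empty cells render as `0 (0.0, 0.0, 0.0)`.
#'
#' @param crosstab A `prs_crosstab`.
#' @return Character vector of lines.
#' @export
render_crosstab <- function(crosstab) {
  stopifnot(inherits(crosstab, "prs_crosstab"))
  cells <- matrix(
    sprintf("%d (%.1f, %.1f, %.1f)",
            crosstab$counts, crosstab$row_pct, crosstab$col_pct,
            crosstab$cell_pct),
    nrow = nrow(crosstab$counts)
  )
  body <- cbind(rownames(crosstab$counts) %||% PRS_BIN_LEVELS, cells)
  header <- c("A \\ B", colnames(crosstab$counts) %||% PRS_BIN_LEVELS)
  widths <- pmax(nchar(header),
                 apply(nchar(body), 2, max))
  fmt_row <- function(row) {
    paste(mapply(formatC, row, width = widths,
                 MoreArgs = list(flag = "-")), collapse = "  ")
  }
  c(fmt_row(header), apply(body, 1, fmt_row))
}

write_key_value <- function(x, path) {
  lines <- vapply(names(x), function(k) {
    sprintf("%s: %s", k, paste(format(x[[k]], digits = 10), collapse = " "))
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Run the full PRS-agreement pipeline
#'
#' Orchestrates the complete analysis from either files on disk or a
#' simulation configuration: sample QC, per-score variant QC and allele
#' harmonization against the post-QC panel, score computation with
#' standardization and percentile bins, LD-aware variant overlap between
#' the two scores, and the full agreement report. Exactly one of
#' `config` or the four input paths must be supplied. With a fixed
#' configuration and seed the run is deterministic end to end; when
#' `out_dir` is given, all artifacts (QC reports, score vectors, overlap
#' pairs, agreement statistics and the rendered cross-classification) are
#' written as plain text.
#'
#' @param config A [sim_config()]; the study is simulated.
#' @param score_a_path,score_b_path,panel_path,cohort_path Paths to the
#'   two scoring files, the dosage panel and the cohort table.
#' @param thresholds Variant-QC thresholds ([qc_thresholds()]).
#' @param r2_threshold,window LD-proxy parameters for the overlap stage.
#' @param cutpoints Top cut-points (percent) for ORs and concordance.
#' @param n_boot Bootstrap replications for AUC/NRI intervals.
#' @param seed Seed for the bootstrap stream (simulation uses the seed
#'   inside `config`).
#' @param out_dir Optional output directory for artifacts.
#' @return A list of class `prs_agreement` with elements `report`
#'   (`prs_concordance`), `overlap` (`ld_overlap`), `scores_a`, `scores_b`,
#'   `qc` (per-stage `qc_report`s) and `n_analyzed`.
#' @export
run_prs_agreement <- function(config = NULL,
                              score_a_path = NULL, score_b_path = NULL,
                              panel_path = NULL, cohort_path = NULL,
                              thresholds = qc_thresholds(),
                              r2_threshold = 0.8, window = 500000,
                              cutpoints = c(1, 5), n_boot = 1000,
                              seed = 1L, out_dir = NULL) {
  paths <- list(score_a_path, score_b_path, panel_path, cohort_path)
  have_paths <- any(!vapply(paths, is.null, logical(1)))
  if (!is.null(config) && have_paths) {
    abort("supply either `config` or input paths, not both")
  }
  if (is.null(config) && !have_paths) {
    abort("supply either `config` or input paths")
  }

  if (!is.null(config)) {
    stopifnot(inherits(config, "sim_config"))
    panel <- generate_panel(config)
    scores <- generate_score_pair(panel, config)
    cohort <- generate_cohort(panel, scores, config)
    score_a <- scores$score_a
    score_b <- scores$score_b
  } else {
    if (any(vapply(paths, is.null, logical(1)))) {
      abort("all four input paths are required")
    }
    score_a <- read_score_file(score_a_path, score_id = "PRS-A")
    score_b <- read_score_file(score_b_path, score_id = "PRS-B")
    panel <- read_dosage_panel(panel_path)
    cohort <- read_cohort(cohort_path)
  }

  sqc <- apply_sample_qc(cohort)
  cohort_qc <- sqc$cohort
  if (nrow(cohort_qc) == 0) abort("sample QC removed every individual")
  panel_qc <- subset_panel_samples(panel, cohort_qc$sample_id)

  vqc_a <- apply_variant_qc(score_a, panel_qc, thresholds)
  vqc_b <- apply_variant_qc(score_b, panel_qc, thresholds)
  harm_a <- harmonize_alleles(vqc_a$score, panel_qc)
  harm_b <- harmonize_alleles(vqc_b$score, panel_qc)

  scores_a <- score_individuals(harm_a$score, panel_qc)
  scores_b <- score_individuals(harm_b$score, panel_qc)

  overlap <- ld_overlap(vqc_a$score, vqc_b$score, panel_qc,
                        r2_threshold = r2_threshold, window = window)
  report <- concordance_report(scores_a, scores_b, cohort_qc,
                               cutpoints = cutpoints, n_boot = n_boot,
                               seed = seed)

  result <- structure(
    list(
      report = report,
      overlap = overlap,
      scores_a = scores_a,
      scores_b = scores_b,
      qc = list(sample = sqc$report,
                variant_a = vqc_a$report, variant_b = vqc_b$report,
                harmonize_a = harm_a$report, harmonize_b = harm_b$report),
      n_analyzed = nrow(cohort_qc)
    ),
    class = "prs_agreement"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_scores <- function(s, name) {
      readr::write_tsv(
        dplyr::mutate(tibble::as_tibble(s),
                      dplyr::across(dplyr::where(is.numeric),
                                    \(x) round(x, 10))),
        file.path(out_dir, name), progress = FALSE)
    }
    write_scores(scores_a, "scores_a.tsv")
    write_scores(scores_b, "scores_b.tsv")
    readr::write_tsv(overlap$pairs, file.path(out_dir, "overlap_pairs.tsv"),
                     progress = FALSE)
    readr::write_lines(render_crosstab(report$crosstab),
                       file.path(out_dir, "crosstab.txt"))
    readr::write_tsv(tidy(report), file.path(out_dir, "concordance.tsv"),
                     progress = FALSE)
    qc_lines <- unlist(lapply(names(result$qc), function(nm) {
      r <- result$qc[[nm]]
      c(sprintf("[%s] input=%d retained=%d", nm, attr(r, "n_input"),
                attr(r, "n_retained")),
        sprintf("%s.%s: %d", nm, r$rule, r$n_removed))
    }))
    readr::write_lines(qc_lines, file.path(out_dir, "qc_report.txt"))
    write_key_value(
      list(n_analyzed = result$n_analyzed,
           n_direct = overlap$n_direct, n_proxy = overlap$n_proxy,
           n_unmatched = overlap$n_unmatched,
           overlap_fraction = overlap$overlap_fraction,
           pearson_r = report$pearson_r,
           topk = report$topk_concordance,
           nri_continuous = report$nri_continuous,
           nri_categorical = report$nri_categorical,
           n_boot = n_boot, seed = seed),
      file.path(out_dir, "summary.txt")
    )
  }
  result
}

#' @export
print.prs_agreement <- function(x, ...) {
  cat(sprintf("<prs_agreement> N analyzed = %d\n", x$n_analyzed))
  print(x$overlap)
  print(x$report)
  invisible(x)
}
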