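#' Percentage matrices for a cross-classification table
#'
#' Given a matrix of counts (rows = bins of the first score, columns = bins
#' of the second), returns row, column and overall percentages, each
#' rounded half-up to one decimal, the convention of published
#' reclassification tables. Empty margins yield 0.0 rather than NaN.
#'
#' @param counts Integer matrix of cross-classification counts.
#' @param digits Decimals to round percentages to (default 1).
#' @return A list with `row_pct`, `col_pct`, `cell_pct` matrices and the
#'   total `n`.
#' @export
crosstab_percentages <- function(counts, digits = 1) {
  counts <- as.matrix(counts)
  n <- sum(counts)
  safe_div <- function(num, den) {
    out <- num / den
    out[den == 0] <- 0
    out
  }
  row_pct <- round_half_up(
    100 * safe_div(counts, matrix(rowSums(counts), nrow(counts),
                                  ncol(counts))), digits)
  col_pct <- round_half_up(
    100 * safe_div(counts, matrix(colSums(counts), nrow(counts),
                                  ncol(counts), byrow = TRUE)), digits)
  cell_pct <- round_half_up(
    100 * safe_div(counts, matrix(n, nrow(counts), ncol(counts))), digits)
  list(row_pct = row_pct, col_pct = col_pct, cell_pct = cell_pct, n = n)
}

new_prs_crosstab <- function(counts, digits = 1) {
  pct <- crosstab_percentages(counts, digits)
  structure(
    list(counts = counts, row_pct = pct$row_pct, col_pct = pct$col_pct,
         cell_pct = pct$cell_pct, n = pct$n),
    class = "prs_crosstab"
  )
}

#' Cross-classify individuals by the percentile bins of two scores
#'
#' Builds the 7 x 7 table of counts of individuals by (bin under score A,
#' bin under score B), with row, column and cell percentages. The diagonal
#' of the `row_pct` matrix reads as "of those in this risk category under
#' A, what percentage is in the same category under B"; its `>=99` entry is
#' the top-1\% concordance.
#'
#' @param a,b `prs_scores` tibbles with bins assigned ([assign_bins()]),
#'   over the same individuals in the same order.
#' @return A `prs_crosstab`.
#' @export
cross_classify <- function(a, b) {
  if (is.null(a$bin) || is.null(b$bin)) {
    abort("assign bins first (see assign_bins())")
  }
  if (nrow(a) != nrow(b)) {
    abort("the two score vectors cover different numbers of individuals")
  }
  if (!is.null(a$sample_id) && !is.null(b$sample_id) &&
      !identical(a$sample_id, b$sample_id)) {
    abort("the two score vectors are not aligned on the same individuals")
  }
  counts <- unclass(table(a$bin, b$bin))
  dimnames(counts) <- list(a_bin = PRS_BIN_LEVELS, b_bin = PRS_BIN_LEVELS)
  new_prs_crosstab(counts)
}

#' @export
print.prs_crosstab <- function(x, ...) {
  cat(sprintf("<prs_crosstab> N = %d; cells are n (row%%, col%%, cell%%)\n",
              x$n))
  cat(render_crosstab(x), sep = "\n")
  invisible(x)
}

#' @export
tidy.prs_crosstab <- function(x, ...) {
  tibble::as_tibble(as.table(x$counts), .name_repair = "minimal") |>
    setNames(c("a_bin", "b_bin", "n")) |>
    dplyr::mutate(
      row_pct = as.vector(x$row_pct),
      col_pct = as.vector(x$col_pct),
      cell_pct = as.vector(x$cell_pct)
    )
}

#' Top-k percent concordance of two scores
#'
#' The fraction of individuals in the top k\% of the first score that are
#' also in the top k\% of the second. Top-k membership is percentile rank
#' (average ties) at or above `100 - k`, which selects exactly `N * k/100`
#' individuals when values are distinct. Symmetric in its arguments when
#' there are no ties at the cut.
#'
#' @param a,b Numeric vectors over the same individuals (or `prs_scores`
#'   tibbles, whose `raw` column is used).
#' @param k_pct Cut, in percent of the population (e.g. 1 or 5).
#' @return A single value in `[0, 1]`.
#' @export
topk_concordance <- function(a, b, k_pct) {
  if (is.data.frame(a)) a <- a$raw
  if (is.data.frame(b)) b <- b$raw
  assert_scalar_number(k_pct, "k_pct", 0, 100, lo_open = TRUE,
                       hi_open = TRUE)
  if (length(a) != length(b)) {
    abort("the two score vectors have different lengths")
  }
  top_a <- percentile_rank(a) >= 100 - k_pct
  if (!any(top_a)) {
    abort(sprintf("no individuals fall in the top %g%%; population too small",
                  k_pct))
  }
  top_b <- percentile_rank(b) >= 100 - k_pct
  mean(top_b[top_a])
}

#' Logistic regression with explicit convergence checks
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares via
#' [stats::glm()]) with a tight convergence tolerance, failing loudly on
#' non-convergence or (quasi-)separation instead of returning unusable
#' Wald statistics.
#'
#' @param formula Model formula; the response must be 0/1.
#' @param data Data frame.
#' @return The fitted `glm` object.
#' @export
fit_logistic <- function(formula, data) {
  y <- stats::model.response(stats::model.frame(formula, data))
  if (length(unique(y)) < 2) {
    abort("both outcome classes must be present")
  }
  fit <- glm(formula, data = data, family = binomial(),
             control = glm.control(epsilon = 1e-10, maxit = 100))
  if (!fit$converged) {
    abort("logistic regression did not converge")
  }
  se <- sqrt(diag(vcov(fit)))
  if (any(!is.finite(se)) || any(abs(coef(fit)) > 15 & se > 100)) {
    abort("logistic regression shows signs of separation; estimates unusable")
  }
  fit
}

# Covariate terms present and non-constant in `data`.
adjustment_terms <- function(data, candidates) {
  keep <- vapply(candidates, function(v) {
    !is.null(data[[v]]) && !anyNA(data[[v]]) &&
      length(unique(data[[v]])) > 1
  }, logical(1))
  candidates[keep]
}

#' Odds ratios at top cut-points versus the middle quintile
#'
#' For each cut-point k, compares individuals in the top k\% of the score
#' against those in the middle quintile (percentiles 40-60), via a
#' multivariable logistic model of the outcome on the top-k indicator
#' adjusted for age, sex, genotyping array and the first five principal
#' components (sex and array are dropped automatically when constant, e.g.
#' in single-sex populations). Wald 95\% confidence intervals.
#'
#' @param scores A `prs_scores` tibble with percentiles assigned.
#' @param cohort Cohort tibble, matched on `sample_id`.
#' @param cutpoints Numeric vector of top cut-points, in percent
#'   (default `c(1, 5)`).
#' @return A tibble with one row per cut-point: `cutpoint`, `or`,
#'   `conf.low`, `conf.high`, `n_top`, `n_ref`, `cases_top`, `cases_ref`.
#' @export
or_at_cutpoints <- function(scores, cohort, cutpoints = c(1, 5)) {
  if (is.null(scores$percentile)) {
    abort("assign percentiles first (see assign_bins())")
  }
  d <- dplyr::inner_join(
    tibble::as_tibble(scores)[c("sample_id", "percentile")],
    cohort, by = "sample_id"
  )
  if (nrow(d) != nrow(scores)) {
    abort("cohort does not cover all scored individuals")
  }
  adj <- adjustment_terms(d, c("age", "sex", "array", paste0("pc", 1:5)))
  purrr::map_dfr(cutpoints, function(k) {
    sub <- d[d$percentile >= 100 - k |
               (d$percentile >= 40 & d$percentile < 60), , drop = FALSE]
    sub$top <- as.integer(sub$percentile >= 100 - k)
    cases_ref <- sum(sub$outcome[sub$top == 0])
    cases_top <- sum(sub$outcome[sub$top == 1])
    if (cases_ref == 0) {
      abort(sprintf(
        "no cases in the middle-quintile reference group at cut-point %g%%", k
      ))
    }
    f <- as.formula(paste("outcome ~ top",
                          paste(c("", adj), collapse = " + ")))
    fit <- fit_logistic(f, sub)
    est <- coef(fit)[["top"]]
    se <- sqrt(vcov(fit)["top", "top"])
    tibble::tibble(
      cutpoint = k,
      or = exp(est),
      conf.low = exp(est - 1.96 * se),
      conf.high = exp(est + 1.96 * se),
      n_top = sum(sub$top == 1), n_ref = sum(sub$top == 0),
      cases_top = cases_top, cases_ref = cases_ref
    )
  })
}

#' Area under the ROC curve by the rank (Mann-Whitney) estimator
#'
#' The probability that a randomly chosen case has a higher predicted risk
#' than a randomly chosen control, with ties counting one half; computed
#' from average ranks, which is exactly the normalized Mann-Whitney
#' U-statistic.
#'
#' @param predicted_risk Numeric vector of predicted risks (any monotone
#'   transform of them gives the same AUC).
#' @param outcome 0/1 vector.
#' @return A single value in `[0, 1]`.
#' @export
auc_mann_whitney <- function(predicted_risk, outcome) {
  if (length(predicted_risk) != length(outcome)) {
    abort("`predicted_risk` and `outcome` have different lengths")
  }
  outcome <- as.integer(outcome)
  n1 <- sum(outcome == 1L)
  n0 <- sum(outcome == 0L)
  if (n1 == 0 || n0 == 0) {
    abort("both outcome classes must be present")
  }
  r <- rank(predicted_risk, ties.method = "average")
  (sum(r[outcome == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Continuous net reclassification improvement
#'
#' Compares predicted risks from an old and an updated model:
#' \deqn{NRI = [P(p_{new} > p_{old} | case) - P(p_{new} < p_{old} | case)]
#'  + [P(p_{new} < p_{old} | control) - P(p_{new} > p_{old} | control)]}
#' Exact ties contribute zero. Ranges over `[-2, 2]`; positive values mean
#' the updated model moves cases up and controls down on balance. Invariant
#' under any strictly increasing transform applied jointly to both risk
#' vectors.
#'
#' @param p_old,p_new Predicted risks under the old and updated model.
#' @param outcome 0/1 vector.
#' @return A single value in `[-2, 2]`.
#' @export
nri_continuous <- function(p_old, p_new, outcome) {
  outcome <- as.integer(outcome)
  if (length(p_old) != length(p_new) ||
      length(p_old) != length(outcome)) {
    abort("inputs have different lengths")
  }
  if (!any(outcome == 1L) || !any(outcome == 0L)) {
    abort("both outcome classes must be present")
  }
  up <- p_new > p_old
  down <- p_new < p_old
  case <- outcome == 1L
  (mean(up[case]) - mean(down[case])) +
    (mean(down[!case]) - mean(up[!case]))
}

#' Categorical net reclassification improvement over percentile bins
#'
#' Same up/down decomposition as [nri_continuous()], with "up" defined as
#' moving to any higher of the seven percentile risk bins and "down" as
#' moving to a lower one.
#'
#' @param bins_old,bins_new Ordered factors of risk bins (as produced by
#'   [assign_bins()]).
#' @param outcome 0/1 vector.
#' @return A single value in `[-2, 2]`.
#' @export
nri_categorical <- function(bins_old, bins_new, outcome) {
  nri_continuous(as.integer(bins_old), as.integer(bins_new), outcome)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples rows (individuals) with replacement `n_boot` times, evaluates
#' `statistic` on each resample, and returns the 2.5/97.5 percentile
#' interval (for `conf = 0.95`). Seeded and reproducible; the caller's RNG
#' stream is untouched.
#'
#' @param data Data frame (rows are resampled) or vector.
#' @param statistic Function of one resampled `data` returning a scalar.
#' @param n_boot Number of bootstrap replications (default 1000).
#' @param seed Seed for the resampling stream.
#' @param conf Coverage of the interval (default 0.95).
#' @return Named numeric `c(lo, hi)`, with the replicate values in the
#'   `"replicates"` attribute.
#' @export
bootstrap_ci <- function(data, statistic, n_boot = 1000, seed = 1L,
                         conf = 0.95) {
  n_boot <- assert_count(n_boot, "n_boot")
  take <- if (is.data.frame(data)) {
    nr <- nrow(data)
    function(idx) data[idx, , drop = FALSE]
  } else {
    nr <- length(data)
    function(idx) data[idx]
  }
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      statistic(take(sample.int(nr, nr, replace = TRUE)))
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE))
  structure(c(lo = ci[1], hi = ci[2]), replicates = reps)
}

auc_with_ci <- function(risk, outcome, n_boot, seed) {
  d <- tibble::tibble(risk = risk, outcome = outcome)
  ci <- bootstrap_ci(d, function(s) auc_mann_whitney(s$risk, s$outcome),
                     n_boot = n_boot, seed = seed)
  c(estimate = auc_mann_whitney(risk, outcome), lo = ci[["lo"]],
    hi = ci[["hi"]])
}

#' Full agreement report for a pair of PRS
#'
#' Computes every between-score agreement statistic for two scores over the
#' same cohort: Pearson correlation of the continuous scores, the 7 x 7
#' percentile cross-classification, top-k\% concordances, odds ratios of
#' the outcome at top cut-points versus the middle quintile for each score,
#' crude AUC (model: score + array + PCs) and multivariable AUC (further
#' adjusted for age and sex) for each score, and the continuous and
#' categorical NRI treating score B as the updated model. Confidence
#' intervals for AUC and NRI come from a percentile bootstrap of
#' individuals over the fitted risks (`n_boot` replications); OR intervals
#' are Wald.
#'
#' @param scores_a,scores_b `prs_scores` tibbles (binned; see
#'   [score_individuals()]) over the same individuals.
#' @param cohort Cohort tibble matched on `sample_id` (already sample-QC'd).
#' @param cutpoints Top cut-points in percent for ORs and concordance
#'   (default `c(1, 5)`).
#' @param n_boot Bootstrap replications for AUC/NRI intervals
#'   (default 1000).
#' @param seed Seed for the bootstrap stream.
#' @return A list of class `prs_concordance`.
#' @export
concordance_report <- function(scores_a, scores_b, cohort,
                               cutpoints = c(1, 5), n_boot = 1000,
                               seed = 1L) {
  for (s in list(scores_a, scores_b)) {
    if (is.null(s$bin) || is.null(s$standardized)) {
      abort("scores must be standardized and binned (see score_individuals())")
    }
  }
  if (!identical(scores_a$sample_id, scores_b$sample_id)) {
    abort("the two score vectors are not aligned on the same individuals")
  }
  d <- dplyr::inner_join(
    dplyr::rename(tibble::as_tibble(scores_a), prs_a_raw = "raw",
                  prs_a = "standardized", percentile_a = "percentile",
                  bin_a = "bin"),
    dplyr::rename(tibble::as_tibble(scores_b), prs_b_raw = "raw",
                  prs_b = "standardized", percentile_b = "percentile",
                  bin_b = "bin"),
    by = "sample_id"
  ) |>
    dplyr::inner_join(cohort, by = "sample_id")
  if (nrow(d) != nrow(scores_a)) {
    abort("cohort does not cover all scored individuals")
  }

  pearson <- cor(d$prs_a, d$prs_b)
  crosstab <- cross_classify(scores_a, scores_b)
  topk <- setNames(
    vapply(cutpoints, function(k) topk_concordance(d$prs_a_raw, d$prs_b_raw,
                                                   k), numeric(1)),
    paste0("top", cutpoints)
  )
  or_a <- or_at_cutpoints(scores_a, cohort, cutpoints)
  or_b <- or_at_cutpoints(scores_b, cohort, cutpoints)

  adj_crude <- adjustment_terms(d, c("array", paste0("pc", 1:5)))
  adj_multi <- adjustment_terms(d, c("age", "sex", "array",
                                     paste0("pc", 1:5)))
  mk_formula <- function(score_term, adj) {
    as.formula(paste("outcome ~", paste(c(score_term, adj),
                                        collapse = " + ")))
  }
  fits <- list(
    crude_a = fit_logistic(mk_formula("prs_a", adj_crude), d),
    crude_b = fit_logistic(mk_formula("prs_b", adj_crude), d),
    multi_a = fit_logistic(mk_formula("prs_a", adj_multi), d),
    multi_b = fit_logistic(mk_formula("prs_b", adj_multi), d)
  )
  risks <- lapply(fits, function(f) unname(predict(f, type = "response")))

  aucs <- list(
    crude_a = auc_with_ci(risks$crude_a, d$outcome, n_boot, seed + 11L),
    crude_b = auc_with_ci(risks$crude_b, d$outcome, n_boot, seed + 12L),
    multi_a = auc_with_ci(risks$multi_a, d$outcome, n_boot, seed + 13L),
    multi_b = auc_with_ci(risks$multi_b, d$outcome, n_boot, seed + 14L)
  )

  nri_dat <- tibble::tibble(p_old = risks$multi_a, p_new = risks$multi_b,
                            bin_old = d$bin_a, bin_new = d$bin_b,
                            outcome = d$outcome)
  nri_cont_est <- nri_continuous(nri_dat$p_old, nri_dat$p_new,
                                 nri_dat$outcome)
  nri_cont_ci <- bootstrap_ci(
    nri_dat, function(s) nri_continuous(s$p_old, s$p_new, s$outcome),
    n_boot = n_boot, seed = seed + 21L
  )
  nri_cat_est <- nri_categorical(nri_dat$bin_old, nri_dat$bin_new,
                                 nri_dat$outcome)
  nri_cat_ci <- bootstrap_ci(
    nri_dat, function(s) nri_categorical(s$bin_old, s$bin_new, s$outcome),
    n_boot = n_boot, seed = seed + 22L
  )

  structure(
    list(
      n = nrow(d),
      score_id_a = attr(scores_a, "score_id"),
      score_id_b = attr(scores_b, "score_id"),
      pearson_r = pearson,
      crosstab = crosstab,
      topk_concordance = topk,
      or_a = or_a, or_b = or_b,
      auc = aucs,
      nri_continuous = c(estimate = nri_cont_est, lo = nri_cont_ci[["lo"]],
                         hi = nri_cont_ci[["hi"]]),
      nri_categorical = c(estimate = nri_cat_est, lo = nri_cat_ci[["lo"]],
                          hi = nri_cat_ci[["hi"]]),
      n_boot = n_boot,
      seed = seed,
      cutpoints = cutpoints
    ),
    class = "prs_concordance"
  )
}

#' @export
print.prs_concordance <- function(x, digits = 3, ...) {
  cat(sprintf("<prs_concordance> %s vs %s, N = %d\n",
              x$score_id_a, x$score_id_b, x$n))
  cat(sprintf("  Pearson r: %.*f\n", digits, x$pearson_r))
  for (k in names(x$topk_concordance)) {
    cat(sprintf("  %s%% concordance: %.1f%%\n",
                sub("^top", "", k), 100 * x$topk_concordance[[k]]))
  }
  fmt_ci <- function(v) sprintf("%.*f (%.*f, %.*f)", digits, v[1], digits,
                                v[2], digits, v[3])
  for (nm in names(x$auc)) {
    cat(sprintf("  AUC %-8s %s\n", paste0(nm, ":"), fmt_ci(x$auc[[nm]])))
  }
  cat(sprintf("  NRI continuous:  %s\n", fmt_ci(x$nri_continuous)))
  cat(sprintf("  NRI categorical: %s\n", fmt_ci(x$nri_categorical)))
  or_line <- function(tab, label) {
    for (i in seq_len(nrow(tab))) {
      cat(sprintf("  OR %s top %g%% vs mid-quintile: %.2f (%.2f, %.2f)\n",
                  label, tab$cutpoint[i], tab$or[i], tab$conf.low[i],
                  tab$conf.high[i]))
    }
  }
  or_line(x$or_a, x$score_id_a)
  or_line(x$or_b, x$score_id_b)
  cat(sprintf("  bootstrap: %d replications, seed %d\n", x$n_boot, x$seed))
  invisible(x)
}

#' @describeIn concordance_report One row per statistic with estimate and
#'   confidence bounds (where computed).
#' @param x A `prs_concordance` object.
#' @param ... Unused.
#' @export
tidy.prs_concordance <- function(x, ...) {
  rows <- list(
    tibble::tibble(statistic = "pearson_r", estimate = x$pearson_r,
                   conf.low = NA_real_, conf.high = NA_real_)
  )
  for (k in names(x$topk_concordance)) {
    rows <- c(rows, list(tibble::tibble(
      statistic = paste0(k, "_concordance"),
      estimate = x$topk_concordance[[k]],
      conf.low = NA_real_, conf.high = NA_real_
    )))
  }
  or_rows <- function(tab, which) {
    purrr::map_dfr(seq_len(nrow(tab)), function(i) {
      tibble::tibble(
        statistic = sprintf("or_%s_top%g", which, tab$cutpoint[i]),
        estimate = tab$or[i], conf.low = tab$conf.low[i],
        conf.high = tab$conf.high[i]
      )
    })
  }
  rows <- c(rows, list(or_rows(x$or_a, "a"), or_rows(x$or_b, "b")))
  for (nm in names(x$auc)) {
    v <- x$auc[[nm]]
    rows <- c(rows, list(tibble::tibble(
      statistic = paste0("auc_", nm), estimate = v[1],
      conf.low = v[2], conf.high = v[3]
    )))
  }
  rows <- c(rows, list(
    tibble::tibble(statistic = "nri_continuous",
                   estimate = x$nri_continuous[1],
                   conf.low = x$nri_continuous[2],
                   conf.high = x$nri_continuous[3]),
    tibble::tibble(statistic = "nri_categorical",
                   estimate = x$nri_categorical[1],
                   conf.low = x$nri_categorical[2],
                   conf.high = x$nri_categorical[3])
  ))
  dplyr::bind_rows(rows)
}

#' @describeIn concordance_report One-row summary of the comparison.
#' @export
glance.prs_concordance <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    pearson_r = x$pearson_r,
    top1_concordance = x$topk_concordance[["top1"]] %||% NA_real_,
    top5_concordance = x$topk_concordance[["top5"]] %||% NA_real_,
    auc_multi_a = x$auc$multi_a[["estimate"]],
    auc_multi_b = x$auc$multi_b[["estimate"]],
    nri_continuous = x$nri_continuous[["estimate"]],
    nri_categorical = x$nri_categorical[["estimate"]],
    n_boot = x$n_boot
  )
}
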