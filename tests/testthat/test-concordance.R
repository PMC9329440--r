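binned <- function(x, ids = as.character(seq_along(x))) {
  assign_bins(tibble::tibble(sample_id = ids, raw = x))
}

test_that("cross-classification of a score with itself is diagonal", {
  set.seed(41)
  s <- binned(rnorm(1000))
  ct <- cross_classify(s, s)
  expect_equal(sum(ct$counts), 1000)
  expect_equal(sum(diag(ct$counts)), 1000)
  expect_equal(diag(ct$row_pct), rep(100, 7), ignore_attr = TRUE)

  # and for independent scores the >=99 diagonal expectation is ~1%
  s2 <- binned(rnorm(1000))
  ct2 <- cross_classify(s, s2)
  expect_equal(sum(ct2$counts), 1000)
  expect_equal(rowSums(ct2$counts), rowSums(ct$counts))
})

test_that("crosstab percentage margins are consistent", {
  set.seed(42)
  a <- binned(rnorm(5000))
  b <- binned(0.6 * a$raw + 0.8 * rnorm(5000))
  ct <- cross_classify(a, b)
  expect_true(all(abs(rowSums(ct$row_pct) - 100) < 0.35))
  expect_true(all(abs(colSums(ct$col_pct) - 100) < 0.35))
  expect_lt(abs(sum(ct$cell_pct) - 100), 2.5)
  # marginals equal the bin-occupancy law
  expect_equal(unname(rowSums(ct$counts)),
               round(5000 * c(1, 19, 20, 20, 20, 19, 1) / 100))
})

test_that("percentages round half up to one decimal, empty margins to 0", {
  counts <- matrix(c(1, 0, 0, 0), nrow = 2)  # second column empty
  pct <- crosstab_percentages(counts)
  expect_equal(pct$col_pct[, 2], c(0, 0))
  expect_equal(pct$row_pct[1, ], c(100, 0))
  # 23.05% must print 23.1 (not banker's 23.0)
  counts2 <- matrix(c(461, 1539, 0, 0), nrow = 1)
  expect_equal(crosstab_percentages(counts2)$cell_pct[1, 1], 23.1)
})

test_that("topk concordance handles identity, symmetry and misalignment", {
  set.seed(43)
  x <- rnorm(2000)
  expect_equal(topk_concordance(x, x, 1), 1.0)
  expect_equal(topk_concordance(x, x, 5), 1.0)
  y <- 0.5 * x + rnorm(2000)
  expect_equal(topk_concordance(x, y, 5), topk_concordance(y, x, 5))
  expect_error(topk_concordance(x, y[1:10], 5), "different lengths")
  expect_error(topk_concordance(x, y, 0), "k_pct")
})

test_that("logistic fits match closed forms and an independent optimizer", {
  # intercept-only at prevalence 1/4
  d <- tibble::tibble(outcome = rep(c(1, 0), c(25, 75)))
  fit <- fit_logistic(outcome ~ 1, d)
  expect_equal(unname(coef(fit)), log(1 / 3), tolerance = 1e-8)

  # 2x2 table (10, 90, 30, 70): OR = 700/2700
  d2 <- tibble::tibble(
    exposed = rep(c(1, 1, 0, 0), c(10, 90, 30, 70)),
    outcome = rep(c(1, 0, 1, 0), c(10, 90, 30, 70))
  )
  fit2 <- fit_logistic(outcome ~ exposed, d2)
  expect_equal(exp(unname(coef(fit2)["exposed"])), (10 * 70) / (90 * 30),
               tolerance = 1e-8)

  # random design vs direct likelihood maximization (independent oracle)
  set.seed(44)
  n <- 400
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.4))
  beta_true <- c(-0.5, 0.8, -0.6)
  y <- rbinom(n, 1, plogis(X %*% beta_true))
  d3 <- tibble::tibble(x1 = X[, 2], x2 = X[, 3], outcome = y)
  fit3 <- fit_logistic(outcome ~ x1 + x2, d3)
  nll <- function(b) {
    eta <- X %*% b
    -sum(y * eta - log1p(exp(eta)))
  }
  grad <- function(b) -drop(t(X) %*% (y - plogis(X %*% b)))
  opt <- optim(c(0, 0, 0), nll, grad, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(unname(coef(fit3)), opt$par, tolerance = 1e-6)

  # degenerate inputs fail loudly
  expect_error(fit_logistic(outcome ~ 1, tibble::tibble(outcome = rep(1, 5))),
               "both outcome classes")
  sep <- tibble::tibble(x = c(1:5, 6:10), outcome = rep(c(0, 1), each = 5))
  expect_error(suppressWarnings(fit_logistic(outcome ~ x, sep)),
               "separation|converge")
})

test_that("AUC equals the brute-force pair enumeration", {
  risk <- c(0.9, 0.8, 0.8, 0.35, 0.3, 0.1)
  outcome <- c(1, 0, 1, 0, 1, 0)
  # oracle: enumerate all case-control pairs, ties count 1/2
  cases <- which(outcome == 1)
  controls <- which(outcome == 0)
  acc <- 0
  for (i in cases) {
    for (j in controls) {
      acc <- acc + (risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j])
    }
  }
  oracle <- acc / (length(cases) * length(controls))
  expect_equal(auc_mann_whitney(risk, outcome), oracle)

  expect_equal(auc_mann_whitney(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  set.seed(45)
  r <- runif(20000)
  y <- rbinom(20000, 1, 0.3)
  expect_equal(auc_mann_whitney(r, y), 0.5, tolerance = 0.01)
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(46)
  risk <- runif(500)
  outcome <- rbinom(500, 1, plogis(3 * risk - 1.5))
  ref <- as.numeric(pROC::auc(pROC::roc(outcome, risk, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc_mann_whitney(risk, outcome), ref, tolerance = 1e-12)
})

test_that("continuous NRI matches direct enumeration and its bounds", {
  p_old <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8)
  p_new <- c(0.2, 0.2, 0.1, 0.5, 0.4, 0.7, 0.6, 0.9)
  outcome <- c(1, 1, 0, 0, 1, 0, 1, 0)
  # oracle: count movements per class explicitly
  up <- p_new > p_old
  dn <- p_new < p_old
  ncase <- sum(outcome); nctrl <- sum(1 - outcome)
  oracle <- (sum(up & outcome == 1) - sum(dn & outcome == 1)) / ncase +
    (sum(dn & outcome == 0) - sum(up & outcome == 0)) / nctrl
  expect_equal(nri_continuous(p_old, p_new, outcome), oracle)

  expect_equal(nri_continuous(p_old, p_old, outcome), 0)
  perfect_new <- ifelse(outcome == 1, p_old + 0.1, p_old - 0.1)
  expect_equal(nri_continuous(p_old, perfect_new, outcome), 2.0)
  # invariant under a joint strictly increasing transform
  expect_equal(nri_continuous(qlogis(p_old), qlogis(p_new), outcome), oracle)
})

test_that("categorical NRI over bins matches enumeration", {
  bins <- factor(c("1-20", "20-40", "40-60", "60-80"),
                 levels = c("1-20", "20-40", "40-60", "60-80"),
                 ordered = TRUE)
  old <- bins[c(1, 2, 3, 4, 1, 2, 3, 4)]
  new <- bins[c(2, 2, 2, 4, 1, 3, 3, 3)]
  outcome <- c(1, 1, 1, 1, 0, 0, 0, 0)
  oracle <- ((1 - 1) / 4) + ((1 - 1) / 4)  # cases: 1 up 1 down; controls: 1 up 1 down
  expect_equal(nri_categorical(old, new, outcome), oracle)

  expect_equal(nri_categorical(old, old, outcome), 0)
  all_up <- bins[c(2, 3, 4, 4, 1, 2, 3, 4)]
  up_only <- nri_categorical(old, all_up, outcome)
  expect_equal(up_only, (3 / 4 - 0 / 4) + 0)  # case 4 cannot move above top bin
})

test_that("bootstrap CIs are seeded, sane and match the closed-form width", {
  d <- tibble::tibble(x = rep(5, 100))
  ci <- bootstrap_ci(d, function(s) mean(s$x), n_boot = 50, seed = 1)
  expect_equal(as.numeric(ci), c(5, 5))

  set.seed(47)
  d2 <- tibble::tibble(x = rnorm(1000))
  ci2 <- bootstrap_ci(d2, function(s) mean(s$x), n_boot = 1000, seed = 9)
  width <- ci2[["hi"]] - ci2[["lo"]]
  expect_equal(width, 2 * 1.96 / sqrt(1000), tolerance = 0.2)

  ci3 <- bootstrap_ci(d2, function(s) mean(s$x), n_boot = 1000, seed = 9)
  expect_identical(ci2, ci3)
})

test_that("the full concordance report is reproducible and coherent", {
  st <- study_no_ld()
  sqc <- apply_sample_qc(st$cohort)
  panel <- prsconcord:::subset_panel_samples(st$panel, sqc$cohort$sample_id)
  sa <- score_individuals(st$scores$score_a, panel)
  sb <- score_individuals(st$scores$score_b, panel)
  rep1 <- concordance_report(sa, sb, sqc$cohort, n_boot = 60, seed = 5)
  rep2 <- concordance_report(sa, sb, sqc$cohort, n_boot = 60, seed = 5)
  expect_identical(tidy(rep1), tidy(rep2))

  td <- tidy(rep1)
  with_ci <- td[!is.na(td$conf.low), ]
  expect_true(all(with_ci$conf.low <= with_ci$estimate + 1e-12 &
                    with_ci$estimate <= with_ci$conf.high + 1e-12))
  expect_true(all(rep1$topk_concordance >= 0 & rep1$topk_concordance <= 1))
  expect_equal(sum(rep1$crosstab$counts), rep1$n)
  expect_gt(rep1$pearson_r, 0.3)
  # a positive genetic effect must separate cases from controls
  expect_gt(rep1$auc$crude_a[["estimate"]], 0.5)
})
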