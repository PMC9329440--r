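test_that("sim_config validates its inputs", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(within_block_corr = 1), "within_block_corr")
  expect_error(sim_config(maf_range = c(0.001, 0.3)), "maf_range")
  expect_error(sim_config(shared_fraction = 1.2), "shared_fraction")
  expect_error(sim_config(n_snps_a = 1000, n_blocks = 5, block_size = 10),
               "exceeds panel")
  expect_error(sim_config(qc_flag_rates = c(related = 0.1)), "qc_flag_rates")
})

test_that("generated dosages are valid genotype counts with the requested MAFs", {
  cfg <- sim_config(n_individuals = 4000, n_blocks = 10, block_size = 5,
                    maf_range = c(0.2, 0.4), n_snps_a = 20, n_snps_b = 20,
                    seed = 11)
  panel <- generate_panel(cfg)
  expect_equal(dim(panel$dosages), c(50, 4000))
  expect_true(all(panel$dosages %in% c(0, 1, 2)))
  maf <- compute_maf(panel)
  # realized MAF within the configured range plus binomial sampling error
  tol <- 4 * sqrt(0.4 * 0.6 / (2 * 4000))
  expect_true(all(maf > 0.2 - tol & maf < 0.4 + tol))
  expect_true(all(panel$variants$info_score > 0.3 &
                    panel$variants$info_score <= 1))
})

test_that("mean dosage follows Hardy-Weinberg expectation 2*MAF", {
  cfg <- sim_config(n_individuals = 20000, n_blocks = 2, block_size = 5,
                    maf_range = c(0.3, 0.3), n_snps_a = 5, n_snps_b = 5,
                    seed = 3)
  panel <- generate_panel(cfg)
  expect_equal(mean(rowMeans(panel$dosages)), 0.6, tolerance = 0.02)
})

test_that("within_block_corr = 0 gives independent variants", {
  cfg <- sim_config(n_individuals = 20000, n_blocks = 2, block_size = 10,
                    within_block_corr = 0, maf_range = c(0.3, 0.3),
                    n_snps_a = 5, n_snps_b = 5, seed = 5)
  panel <- generate_panel(cfg)
  r2_adj <- vapply(1:9, function(i) {
    cor(panel$dosages[i, ], panel$dosages[i + 1, ])^2
  }, numeric(1))
  expect_true(all(r2_adj < 0.01))
})

test_that("adjacent-pair dosage R2 matches the latent-threshold prediction", {
  # the closed-form phi coefficient of two thresholded latents is the
  # independent oracle for the LD the generator induces
  cfg <- sim_config(n_individuals = 20000, n_blocks = 5, block_size = 2,
                    within_block_corr = 0.95, maf_range = c(0.3, 0.3),
                    n_snps_a = 5, n_snps_b = 5, seed = 8)
  panel <- generate_panel(cfg)
  r2 <- vapply(seq_len(5), function(b) {
    i <- (b - 1) * 2 + 1
    cor(panel$dosages[i, ], panel$dosages[i + 1, ])^2
  }, numeric(1))
  predicted <- prsconcord:::dosage_corr_from_latent(0.95, 0.3)^2
  expect_equal(mean(r2), predicted, tolerance = 0.05)
  # and the inverse map reaches a target dosage-scale R2 > 0.8
  latent <- latent_corr_for_dosage_r2(0.85, maf = 0.3)
  cfg2 <- sim_config(n_individuals = 20000, n_blocks = 5, block_size = 2,
                     within_block_corr = latent, maf_range = c(0.3, 0.3),
                     n_snps_a = 5, n_snps_b = 5, seed = 9)
  panel2 <- generate_panel(cfg2)
  r2_strong <- vapply(seq_len(5), function(b) {
    i <- (b - 1) * 2 + 1
    cor(panel2$dosages[i, ], panel2$dosages[i + 1, ])^2
  }, numeric(1))
  expect_gt(mean(r2_strong), 0.8)
})

test_that("identical seeds reproduce the study bit for bit", {
  cfg <- sim_config(n_individuals = 500, n_blocks = 5, block_size = 4,
                    n_snps_a = 10, n_snps_b = 10, seed = 123)
  p1 <- generate_panel(cfg)
  p2 <- generate_panel(cfg)
  expect_identical(p1, p2)
  s1 <- generate_score_pair(p1, cfg)
  s2 <- generate_score_pair(p2, cfg)
  expect_identical(s1, s2)
  c1 <- generate_cohort(p1, s1, cfg)
  c2 <- generate_cohort(p2, s2, cfg)
  expect_identical(c1, c2)
})

test_that("score pair overlap obeys shared_fraction", {
  cfg <- sim_config(n_individuals = 100, n_blocks = 41, block_size = 10,
                    n_snps_a = 313, n_snps_b = 313, shared_fraction = 0.72,
                    seed = 6)
  panel <- generate_panel(cfg)
  scores <- generate_score_pair(panel, cfg)
  shared <- intersect(scores$score_a$variant_id, scores$score_b$variant_id)
  expect_equal(length(shared), 225)  # round(0.72 * 313)

  cfg0 <- sim_config(n_individuals = 100, n_blocks = 41, block_size = 10,
                     n_snps_a = 50, n_snps_b = 50, shared_fraction = 0,
                     seed = 6)
  s0 <- generate_score_pair(panel, cfg0)
  expect_length(intersect(s0$score_a$variant_id, s0$score_b$variant_id), 0)
})

test_that("degenerate full-overlap configuration gives identical scores", {
  cfg <- sim_config(n_individuals = 600, n_blocks = 10, block_size = 5,
                    n_snps_a = 20, n_snps_b = 20, shared_fraction = 1,
                    weight_corr = 1, seed = 21)
  panel <- generate_panel(cfg)
  scores <- generate_score_pair(panel, cfg)
  a <- dplyr::arrange(tibble::as_tibble(scores$score_a), variant_id)
  b <- dplyr::arrange(tibble::as_tibble(scores$score_b), variant_id)
  expect_equal(a$variant_id, b$variant_id)
  expect_equal(a$weight, b$weight)
  sa <- score_individuals(scores$score_a, panel)
  sb <- score_individuals(scores$score_b, panel)
  expect_equal(sa$standardized, sb$standardized, tolerance = 1e-12)
})

test_that("solved intercept hits the target prevalence", {
  cfg <- sim_config(n_individuals = 20000, n_blocks = 10, block_size = 5,
                    n_snps_a = 30, n_snps_b = 30,
                    prevalence_target = 0.05, seed = 31)
  panel <- generate_panel(cfg)
  scores <- generate_score_pair(panel, cfg)
  cohort <- generate_cohort(panel, scores, cfg)
  expect_lt(abs(mean(cohort$outcome) - 0.05), 0.005)
})

test_that("threshold outcome mode binarizes a quantitative trait", {
  cfg <- sim_config(n_individuals = 5000, n_blocks = 10, block_size = 5,
                    n_snps_a = 30, n_snps_b = 30,
                    outcome_mode = "threshold", trait_mean = 138,
                    trait_sd = 15, trait_threshold = 140, seed = 32)
  panel <- generate_panel(cfg)
  scores <- generate_score_pair(panel, cfg)
  cohort <- generate_cohort(panel, scores, cfg)
  truth <- attr(cohort, "truth")
  expect_identical(cohort$outcome, as.integer(truth$trait >= 140))
  expect_gt(mean(cohort$outcome), 0.2)
  expect_lt(mean(cohort$outcome), 0.8)
})

test_that("zero flag rates plant no sample-QC exclusions", {
  cfg <- sim_config(n_individuals = 2000, n_blocks = 5, block_size = 4,
                    n_snps_a = 10, n_snps_b = 10,
                    qc_flag_rates = c(sex_discordant = 0, related = 0,
                                      het_miss_outlier = 0), seed = 33)
  panel <- generate_panel(cfg)
  scores <- generate_score_pair(panel, cfg)
  cohort <- generate_cohort(panel, scores, cfg)
  res <- apply_sample_qc(cohort)
  expect_equal(nrow(res$cohort), 2000)
  expect_equal(sum(res$report$n_removed), 0)
})

test_that("induced score correlation is monotone in overlap and weight correlation", {
  cfg_base <- sim_config(n_individuals = 20000, n_blocks = 40,
                         block_size = 10, within_block_corr = 0,
                         n_snps_a = 150, n_snps_b = 150, seed = 77)
  panel <- generate_panel(cfg_base)
  grid <- expand.grid(sf = c(0.2, 0.6, 1), wc = c(0.2, 0.6, 1))
  r <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- sim_config(n_individuals = 20000, n_blocks = 40, block_size = 10,
                      within_block_corr = 0, n_snps_a = 150, n_snps_b = 150,
                      shared_fraction = grid$sf[i], weight_corr = grid$wc[i],
                      seed = 77)
    s <- generate_score_pair(panel, cfg)
    cor(compute_prs(s$score_a, panel)$raw,
        compute_prs(s$score_b, panel)$raw)
  }, numeric(1))
  m <- matrix(r, nrow = 3)  # rows: shared_fraction, cols: weight_corr
  expect_true(all(diff(m[, 3]) > 0))   # increasing in shared_fraction
  expect_true(all(diff(m[3, ]) > 0))   # increasing in weight_corr
  expect_true(all(apply(m, 2, diff) > -0.02))
  expect_true(all(apply(t(m), 2, diff) > -0.02))
})
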