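test_that("MAF is the folded counted-allele frequency", {
  panel <- tiny_panel(matrix(c(0, 0, 0,
                               2, 2, 2,
                               1, 1, 1), nrow = 3, byrow = TRUE))
  maf <- compute_maf(panel)
  expect_equal(unname(maf), c(0, 0, 0.5))
  p4 <- tiny_panel(matrix(c(0, 1, 2, 1), nrow = 1))
  expect_equal(unname(compute_maf(p4)), 0.5)
  empty <- dosage_panel(tiny_panel()$variants,
                        matrix(numeric(), nrow = 2, ncol = 0),
                        character())
  expect_error(compute_maf(empty), "no individuals")
})

test_that("variant QC rules fire exactly as specified", {
  # variant 1: A/T at MAF 0.495 (ambiguous); variant 2: A/T at MAF 0.30
  # (palindromic but retained: the rule applies only above 0.49);
  # variant 3: G/C at MAF 0.004 (rare); variant 4: clean but info <= 0.4;
  # variant 5: clean
  n <- 1000
  mk_dos <- function(maf) {
    d <- rep(0, n)
    d[seq_len(round(2 * maf * n))] <- 1
    d
  }
  dos <- rbind(mk_dos(0.495), mk_dos(0.30), mk_dos(0.004), mk_dos(0.25),
               mk_dos(0.25))
  panel <- tiny_panel(
    dos,
    alleles = list(c("A", "T"), c("A", "T"), c("G", "C"), c("A", "G"),
                   c("T", "C")),
    info = c(0.9, 0.9, 0.9, 0.40, 0.9)
  )
  score <- tiny_score(panel, weights = rep(0.1, 5))
  res <- apply_variant_qc(score, panel)
  expect_identical(res$score$variant_id, c("rs2", "rs5"))
  removed <- setNames(res$report$n_removed, res$report$rule)
  expect_equal(removed[["ambiguous"]], 1L)
  expect_equal(removed[["rare"]], 1L)
  expect_equal(removed[["low_info"]], 1L)
  expect_equal(removed[["unmatched"]], 0L)
  expect_equal(attr(res$report, "n_input") - sum(res$report$n_removed),
               attr(res$report, "n_retained"))
})

test_that("variant QC is idempotent and counts unmatched variants", {
  rp <- random_panel_scores(n_var = 30, n_ind = 400)
  extra <- tibble::tibble(variant_id = "rs_missing", chromosome = "9",
                          position = 1L, effect_allele = "A",
                          other_allele = "G", weight = 0.3)
  score <- score_file(dplyr::bind_rows(tibble::as_tibble(rp$score), extra))
  r1 <- apply_variant_qc(score, rp$panel)
  r2 <- apply_variant_qc(r1$score, rp$panel)
  expect_identical(tibble::as_tibble(r2$score), tibble::as_tibble(r1$score))
  expect_equal(sum(r2$report$n_removed), 0)
  removed <- setNames(r1$report$n_removed, r1$report$rule)
  expect_equal(removed[["unmatched"]], 1L)
})

test_that("harmonization aligns, complements and strand-resolves alleles", {
  dos <- matrix(c(0, 1, 2, 2), nrow = 1)
  panel <- tiny_panel(dos, alleles = list(c("A", "G")))

  # identity: effect allele is the counted allele
  s_id <- tiny_score(panel, 0.5)
  h_id <- harmonize_alleles(s_id, panel)
  expect_false(h_id$score$flip_dosage)

  # swapped: effect = panel allele2 -> dosage complemented; the resulting
  # score equals the identity-case score with weight -beta, up to the
  # additive constant 2*beta (beta*(2-d) == 2*beta - beta*d)
  s_sw <- tiny_score(panel, 0.5, effect = "G", other = "A")
  h_sw <- harmonize_alleles(s_sw, panel)
  expect_true(h_sw$score$flip_dosage)
  prs_sw <- compute_prs(h_sw$score, panel)
  prs_neg <- compute_prs(tiny_score(panel, -0.5), panel)
  expect_equal(prs_sw$raw, 2 * 0.5 + prs_neg$raw, tolerance = 1e-12)

  # strand flip: A/C written as T/G against a T/G... use non-palindromic
  panel2 <- tiny_panel(dos, alleles = list(c("T", "G")))
  s_strand <- tiny_score(panel2, 0.5, effect = "A", other = "C")
  h_strand <- harmonize_alleles(s_strand, panel2)
  expect_equal(nrow(h_strand$score), 1)
  expect_false(h_strand$score$flip_dosage)
  expect_equal(attr(h_strand$report, "n_strand_resolved"), 1L)

  # irreconcilable alleles are dropped and reported
  s_bad <- tiny_score(panel, 0.5, effect = "A", other = "C")
  h_bad <- harmonize_alleles(s_bad, panel)
  expect_equal(nrow(h_bad$score), 0)
  removed <- setNames(h_bad$report$n_removed, h_bad$report$rule)
  expect_equal(removed[["allele_mismatch"]], 1L)
})

test_that("planted allele swaps and strand flips leave the standardized score invariant", {
  cfg <- sim_config(n_individuals = 1500, n_blocks = 10, block_size = 6,
                    n_snps_a = 40, n_snps_b = 40, shared_fraction = 1,
                    weight_corr = 1, n_plant_swapped = 8,
                    n_plant_strand_flip = 5, seed = 55)
  panel <- generate_panel(cfg)
  scores <- generate_score_pair(panel, cfg)
  planted <- attr(scores$score_a, "planted")
  expect_length(planted$swapped, 8)
  expect_length(planted$strand_flipped, 5)
  # score B carries the same variants and weights without any planting
  sa <- score_individuals(scores$score_a, panel)
  sb <- score_individuals(scores$score_b, panel)
  expect_equal(sa$standardized, sb$standardized, tolerance = 1e-10)
})

test_that("sample QC removes flagged individuals and warns on empty cohorts", {
  cohort <- tibble::tibble(
    sample_id = paste0("s", 1:10),
    outcome = rep(0:1, 5),
    age = 50, sex = "female", array = "axiom",
    pc1 = 0, pc2 = 0, pc3 = 0, pc4 = 0, pc5 = 0,
    sex_discordant = c(TRUE, rep(FALSE, 9)),
    related = c(FALSE, TRUE, TRUE, rep(FALSE, 7)),
    het_miss_outlier = FALSE
  )
  res <- apply_sample_qc(cohort)
  expect_equal(nrow(res$cohort), 7)
  expect_equal(sum(res$report$n_removed), 3)
  expect_equal(attr(res$report, "n_retained"), 7L)

  none <- dplyr::mutate(cohort, sex_discordant = FALSE, related = FALSE)
  expect_equal(nrow(apply_sample_qc(none)$cohort), 10)

  all_flagged <- dplyr::mutate(cohort, related = TRUE)
  expect_warning(res_all <- apply_sample_qc(all_flagged), "every individual")
  expect_equal(nrow(res_all$cohort), 0)
})

test_that("planted QC variant counts are reported exactly", {
  cfg <- sim_config(n_individuals = 20000, n_blocks = 12, block_size = 10,
                    maf_range = c(0.05, 0.45), info_range = c(0.45, 1),
                    n_snps_a = 60, n_snps_b = 60,
                    n_plant_ambiguous = 5, n_plant_rare = 4,
                    n_plant_low_info = 3, seed = 2024)
  panel <- generate_panel(cfg)
  scores <- generate_score_pair(panel, cfg)
  res <- apply_variant_qc(scores$score_a, panel)
  removed <- setNames(res$report$n_removed, res$report$rule)
  expect_equal(removed[["ambiguous"]], 5L)
  expect_equal(removed[["rare"]], 4L)
  expect_equal(removed[["low_info"]], 3L)
  expect_equal(removed[["unmatched"]], 0L)
  expect_equal(attr(res$report, "n_retained"), 48L)
  # idempotent on the fixture too
  res2 <- apply_variant_qc(res$score, panel)
  expect_equal(sum(res2$report$n_removed), 0)
})
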