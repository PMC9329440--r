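#' Configuration for the synthetic PRS study generator
#'
#' Collects every knob of the simulated study: cohort size, LD-block
#' structure of the genotype panel, the sizes and overlap of the two scoring
#' files, the disease model, and the rates at which sample-QC flags and
#' problematic variants are planted. The defaults describe a mid-sized
#' biobank-style cohort: 20,000 individuals, 500 variants in 50 LD blocks,
#' two scores sharing 70\% of their variants with strongly correlated
#' weights, and a binary outcome at 5\% prevalence driven by the genetic
#' score plus age and sex.
#'
#' @param n_individuals Number of individuals in the cohort.
#' @param n_blocks,block_size LD structure: the panel holds
#'   `n_blocks * block_size` variants; variants within a block are generated
#'   from a shared latent Gaussian with AR(1) correlation
#'   `within_block_corr`, variants in different blocks are independent.
#' @param within_block_corr Latent autoregressive correlation in `[0, 1)`.
#'   Note the correlation of the resulting hard-call dosages is attenuated
#'   relative to the latent value (see [latent_corr_for_dosage_r2()]).
#' @param maf_range Length-2 numeric; per-variant minor allele frequencies
#'   are drawn uniformly from this interval, which must sit inside
#'   `(0.005, 0.5]`.
#' @param n_snps_a,n_snps_b Number of variants in each scoring file.
#' @param shared_fraction Fraction of score-A variants that also carry a
#'   weight in score B.
#' @param weight_corr Correlation of the effect sizes on shared variants.
#' @param disease_model Named list with elements `intercept`, `beta_prs`,
#'   `beta_age`, `beta_sex`, all on the log-odds scale. `beta_age` applies
#'   to age standardized to mean 0 / sd 1; `beta_sex` to an indicator of
#'   male sex. `intercept = NULL` means: solve it so that the marginal case
#'   fraction matches `prevalence_target`.
#' @param prevalence_target Target marginal disease prevalence in `(0, 1)`;
#'   used only when `disease_model$intercept` is `NULL`.
#' @param qc_flag_rates Named numeric: independent per-individual
#'   probabilities for the `sex_discordant`, `related` and
#'   `het_miss_outlier` sample-QC flags.
#' @param n_plant_ambiguous,n_plant_rare,n_plant_low_info Number of variants
#'   deliberately planted so each variant-QC rule has known work to do:
#'   palindromic (A/T or C/G) variants at allele frequency 0.5, variants at
#'   minor allele frequency 0.002, and variants with imputation info score
#'   in (0.30, 0.40]. The planted sets are disjoint and are always included
#'   in score A.
#' @param n_plant_swapped Number of score-A entries written with effect and
#'   other allele exchanged and the weight sign-flipped; harmonization must
#'   undo this without changing the standardized score.
#' @param n_plant_strand_flip Number of score-A entries written on the
#'   opposite strand (both alleles complemented); only ever planted on
#'   non-palindromic variants so they are resolvable.
#' @param dosage_noise Half-width of uniform noise added to hard genotype
#'   calls to mimic non-integer imputed dosages (result clipped to
#'   `[0, 2]`); default 0 keeps hard calls.
#' @param info_range Range of the simulated per-variant imputation info
#'   scores (metadata only; the pipeline thresholds but never recomputes
#'   them).
#' @param sex_mode `"both"` simulates an even sex split; `"female_only"`
#'   mimics a breast-cancer-style population (sex then drops out of all
#'   adjusted models).
#' @param outcome_mode `"binary"` draws the outcome from the logistic
#'   disease model; `"threshold"` simulates a quantitative trait
#'   (systolic-blood-pressure-like, mean `trait_mean`, residual sd
#'   `trait_sd`) and defines the outcome as trait >= `trait_threshold`,
#'   mimicking hypertension defined as SBP >= 140.
#' @param trait_mean,trait_sd,trait_threshold Quantitative-trait parameters
#'   for `outcome_mode = "threshold"`.
#' @param seed Master seed; all generator components derive fixed
#'   sub-streams from it, so the same configuration reproduces the same
#'   study bit for bit.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 20000,
                       n_blocks = 50,
                       block_size = 10,
                       within_block_corr = 0.9,
                       maf_range = c(0.05, 0.5),
                       n_snps_a = 100,
                       n_snps_b = 100,
                       shared_fraction = 0.7,
                       weight_corr = 0.9,
                       disease_model = list(intercept = NULL, beta_prs = 0.5,
                                            beta_age = 0.3, beta_sex = 0.2),
                       prevalence_target = 0.05,
                       qc_flag_rates = c(sex_discordant = 0.002,
                                         related = 0.03,
                                         het_miss_outlier = 0.005),
                       n_plant_ambiguous = 0,
                       n_plant_rare = 0,
                       n_plant_low_info = 0,
                       n_plant_swapped = 0,
                       n_plant_strand_flip = 0,
                       dosage_noise = 0,
                       info_range = c(0.3, 1),
                       sex_mode = c("both", "female_only"),
                       outcome_mode = c("binary", "threshold"),
                       trait_mean = 138,
                       trait_sd = 15,
                       trait_threshold = 140,
                       seed = 1L) {
  sex_mode <- match.arg(sex_mode)
  outcome_mode <- match.arg(outcome_mode)
  n_individuals <- assert_count(n_individuals, "n_individuals")
  n_blocks <- assert_count(n_blocks, "n_blocks")
  block_size <- assert_count(block_size, "block_size")
  assert_scalar_number(within_block_corr, "within_block_corr", 0, 1,
                       hi_open = TRUE)
  if (!is.numeric(maf_range) || length(maf_range) != 2 ||
      maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0.005 - 1e-12 || maf_range[2] > 0.5) {
    abort("`maf_range` must be an increasing pair inside (0.005, 0.5]")
  }
  n_snps_a <- assert_count(n_snps_a, "n_snps_a")
  n_snps_b <- assert_count(n_snps_b, "n_snps_b")
  assert_scalar_number(shared_fraction, "shared_fraction", 0, 1)
  assert_scalar_number(weight_corr, "weight_corr", -1, 1)
  assert_scalar_number(prevalence_target, "prevalence_target", 0, 1,
                       lo_open = TRUE, hi_open = TRUE)
  stopifnot(is.list(disease_model))
  for (nm in c("beta_prs", "beta_age", "beta_sex")) {
    if (is.null(disease_model[[nm]])) {
      abort(sprintf("`disease_model$%s` is required", nm))
    }
  }
  flags <- c("sex_discordant", "related", "het_miss_outlier")
  if (!all(flags %in% names(qc_flag_rates))) {
    abort("`qc_flag_rates` must name sex_discordant, related, het_miss_outlier")
  }
  if (any(qc_flag_rates < 0 | qc_flag_rates > 1)) {
    abort("`qc_flag_rates` must lie in [0, 1]")
  }
  assert_scalar_number(dosage_noise, "dosage_noise", 0, 1)
  n_plant_ambiguous <- assert_count(n_plant_ambiguous, "n_plant_ambiguous", 0L)
  n_plant_rare <- assert_count(n_plant_rare, "n_plant_rare", 0L)
  n_plant_low_info <- assert_count(n_plant_low_info, "n_plant_low_info", 0L)
  n_plant_swapped <- assert_count(n_plant_swapped, "n_plant_swapped", 0L)
  n_plant_strand_flip <- assert_count(n_plant_strand_flip,
                                      "n_plant_strand_flip", 0L)
  n_var <- n_blocks * block_size
  n_planted <- n_plant_ambiguous + n_plant_rare + n_plant_low_info
  if (n_planted > n_var) {
    abort("planted QC variants exceed the panel size")
  }
  if (n_snps_a > n_var) {
    abort(sprintf("n_snps_a (%d) exceeds panel variant count (%d)",
                  n_snps_a, n_var))
  }
  if (n_planted > n_snps_a) {
    abort("planted QC variants exceed n_snps_a (they must all fit in score A)")
  }
  seed <- assert_count(seed, "seed", 0L)
  if (seed > 2^31 - 10) abort("`seed` must be below 2^31 - 10")

  structure(
    list(
      n_individuals = n_individuals, n_blocks = n_blocks,
      block_size = block_size, within_block_corr = within_block_corr,
      maf_range = as.numeric(maf_range), n_snps_a = n_snps_a,
      n_snps_b = n_snps_b, shared_fraction = shared_fraction,
      weight_corr = weight_corr, disease_model = disease_model,
      prevalence_target = prevalence_target,
      qc_flag_rates = qc_flag_rates[flags],
      n_plant_ambiguous = n_plant_ambiguous, n_plant_rare = n_plant_rare,
      n_plant_low_info = n_plant_low_info,
      n_plant_swapped = n_plant_swapped,
      n_plant_strand_flip = n_plant_strand_flip,
      dosage_noise = dosage_noise, info_range = as.numeric(info_range),
      sex_mode = sex_mode, outcome_mode = outcome_mode,
      trait_mean = trait_mean, trait_sd = trait_sd,
      trait_threshold = trait_threshold, seed = seed
    ),
    class = "sim_config"
  )
}

# Fixed per-component sub-stream offsets off the master seed.
sim_seed <- function(config, component) {
  offsets <- c(panel = 1L, scores = 2L, cohort = 3L)
  config$seed + offsets[[component]]
}

# Non-palindromic allele pairs used for ordinary variants, so that the
# palindromic-SNP QC rule fires only on deliberately planted variants.
NONPALINDROMIC_PAIRS <- matrix(
  c("A", "C", "A", "G", "C", "A", "C", "T",
    "G", "A", "G", "T", "T", "C", "T", "G"),
  ncol = 2, byrow = TRUE
)

#' Generate an LD-block-structured genotype dosage panel
#'
#' Variants are generated per block from a latent multivariate Gaussian with
#' AR(1) correlation, thresholded at each variant's allele frequency on two
#' independent haplotypes, so genotypes satisfy Hardy-Weinberg expectations
#' and adjacent variants within a block are in LD that decays with distance.
#' `allele1` is the dosage-counted allele (frequency drawn from
#' `maf_range`); `allele2` is the other allele. Imputation info scores are
#' simulated metadata drawn uniformly from `config$info_range`.
#'
#' Planted variants (see [sim_config()]) get deterministic roles: palindromic
#' alleles at frequency 0.5, minor allele frequency 0.002, or info score in
#' (0.30, 0.40]. Their variant ids are recorded in the `"planted"`
#' attribute of the returned panel.
#'
#' @param config A [sim_config()].
#' @return A `dosage_panel` (see [dosage_panel()]).
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(sim_seed(config, "panel"), {
    n <- config$n_individuals
    n_var <- config$n_blocks * config$block_size
    rho <- config$within_block_corr

    planted_idx <- sample.int(
      n_var,
      config$n_plant_ambiguous + config$n_plant_rare + config$n_plant_low_info
    )
    idx_amb <- planted_idx[seq_len(config$n_plant_ambiguous)]
    idx_rare <- planted_idx[config$n_plant_ambiguous +
                              seq_len(config$n_plant_rare)]
    idx_low <- planted_idx[config$n_plant_ambiguous + config$n_plant_rare +
                             seq_len(config$n_plant_low_info)]

    p <- runif(n_var, config$maf_range[1], config$maf_range[2])
    p[idx_amb] <- 0.5
    p[idx_rare] <- 0.002

    info <- runif(n_var, config$info_range[1], config$info_range[2])
    info[idx_low] <- runif(length(idx_low), 0.30, 0.40)

    pair_idx <- sample.int(nrow(NONPALINDROMIC_PAIRS), n_var, replace = TRUE)
    allele1 <- NONPALINDROMIC_PAIRS[pair_idx, 1]
    allele2 <- NONPALINDROMIC_PAIRS[pair_idx, 2]
    amb_pairs <- matrix(c("A", "T", "C", "G"), ncol = 2, byrow = TRUE)
    if (length(idx_amb)) {
      k <- sample.int(2, length(idx_amb), replace = TRUE)
      allele1[idx_amb] <- amb_pairs[k, 1]
      allele2[idx_amb] <- amb_pairs[k, 2]
    }

    # One AR(1) latent Gaussian per haplotype per block; allele indicator by
    # thresholding at the variant's allele frequency; dosage = sum of the
    # two haplotypes.
    dos <- matrix(0L, nrow = n_var, ncol = n)
    for (b in seq_len(config$n_blocks)) {
      rows <- (b - 1L) * config$block_size + seq_len(config$block_size)
      thr <- qnorm(p[rows])
      for (h in 1:2) {
        z <- matrix(rnorm(n * config$block_size), nrow = n)
        if (rho > 0 && config$block_size > 1) {
          for (k in 2:config$block_size) {
            z[, k] <- rho * z[, k - 1] + sqrt(1 - rho^2) * z[, k]
          }
        }
        dos[rows, ] <- dos[rows, ] +
          t(sweep(z, 2, thr, `<`)) * 1L
      }
    }
    dosages <- dos * 1.0
    if (config$dosage_noise > 0) {
      dosages <- dosages +
        matrix(runif(length(dosages), -config$dosage_noise,
                     config$dosage_noise), nrow = n_var)
      dosages <- pmin(2, pmax(0, dosages))
    }

    block <- rep(seq_len(config$n_blocks), each = config$block_size)
    within <- rep(seq_len(config$block_size), times = config$n_blocks)
    chrom <- as.character(1L + (block - 1L) %% 22L)
    # blocks on the same chromosome are spaced 2 Mb apart (beyond any proxy
    # search window); variants within a block sit 5 kb apart
    block_on_chr <- ((block - 1L) %/% 22L)
    pos <- block_on_chr * 2000000L + (within - 1L) * 5000L + 1L

    variants <- tibble::tibble(
      variant_id = sprintf("rs%06d", seq_len(n_var)),
      chromosome = chrom,
      position = as.integer(pos),
      allele1 = allele1,
      allele2 = allele2,
      info_score = info
    )
    panel <- dosage_panel(
      variants = variants,
      dosages = dosages,
      sample_ids = sprintf("id%06d", seq_len(n))
    )
    attr(panel, "planted") <- list(
      ambiguous = variants$variant_id[idx_amb],
      rare = variants$variant_id[idx_rare],
      low_info = variants$variant_id[idx_low]
    )
    panel
  })
}

#' Generate a pair of scoring files with controlled overlap
#'
#' Score A receives `n_snps_a` panel variants (always including any planted
#' QC variants); score B shares `round(shared_fraction * n_snps_a)` of them
#' and draws the remainder of its `n_snps_b` variants from the rest of the
#' panel. Effect sizes are Gaussian; on shared variants the score-B weight
#' is correlated with the score-A weight at `weight_corr` (exactly equal
#' when `weight_corr = 1`). Optionally plants allele-order swaps
#' (effect/other exchanged, weight negated) and strand flips in score A to
#' exercise harmonization; planted entry ids are recorded in the
#' `"planted"` attribute of score A.
#'
#' @param panel A `dosage_panel` from [generate_panel()].
#' @param config The same [sim_config()] used for the panel.
#' @return A list with elements `score_a` and `score_b`, each a
#'   [score_file()].
#' @export
generate_score_pair <- function(panel, config) {
  stopifnot(inherits(config, "sim_config"), inherits(panel, "dosage_panel"))
  with_seed(sim_seed(config, "scores"), {
    v <- panel$variants
    n_var <- nrow(v)
    n_shared <- round(config$shared_fraction * config$n_snps_a)
    n_extra_b <- config$n_snps_b - n_shared
    if (n_extra_b < 0) {
      abort("n_snps_b is smaller than the implied number of shared variants")
    }
    if (config$n_snps_a + n_extra_b > n_var) {
      abort(sprintf(
        "panel has %d variants but the scores need %d; enlarge the panel",
        n_var, config$n_snps_a + n_extra_b
      ))
    }

    planted <- attr(panel, "planted") %||%
      list(ambiguous = character(), rare = character(), low_info = character())
    planted_ids <- unlist(planted, use.names = FALSE)
    free_idx <- which(!(v$variant_id %in% planted_ids))
    idx_a <- c(match(planted_ids, v$variant_id),
               sample(free_idx, config$n_snps_a - length(planted_ids)))
    idx_a <- sample(idx_a)  # shuffle so planted variants are interleaved
    idx_shared <- if (n_shared > 0) sample(idx_a, n_shared) else integer()
    idx_b_extra <- if (n_extra_b > 0) {
      sample(setdiff(seq_len(n_var), idx_a), n_extra_b)
    } else {
      integer()
    }
    idx_b <- c(idx_shared, idx_b_extra)

    w_sd <- 0.1
    beta_a <- rnorm(config$n_snps_a, 0, w_sd)
    beta_b <- numeric(length(idx_b))
    if (n_shared > 0) {
      ba_shared <- beta_a[match(idx_shared, idx_a)]
      wc <- config$weight_corr
      beta_b[seq_len(n_shared)] <- wc * ba_shared +
        sqrt(1 - wc^2) * rnorm(n_shared, 0, w_sd)
    }
    if (n_extra_b > 0) {
      beta_b[n_shared + seq_len(n_extra_b)] <- rnorm(n_extra_b, 0, w_sd)
    }

    make_score <- function(idx, beta, id) {
      tibble::tibble(
        variant_id = v$variant_id[idx],
        chromosome = v$chromosome[idx],
        position = v$position[idx],
        effect_allele = v$allele1[idx],
        other_allele = v$allele2[idx],
        weight = beta
      ) |>
        score_file(score_id = id, trait_label = "synthetic trait")
    }
    score_a <- make_score(idx_a, beta_a, "PRS-A")
    score_b <- make_score(idx_b, beta_b, "PRS-B")

    # plant harmonization work in score A: allele-order swaps (weight
    # negated -> same score up to an additive constant) and strand flips
    # (complemented alleles; only on non-palindromic variants, which is all
    # non-planted-ambiguous variants here)
    swappable <- which(!(score_a$variant_id %in% planted$ambiguous))
    n_swap <- min(config$n_plant_swapped, length(swappable))
    n_strand <- min(config$n_plant_strand_flip, length(swappable) - n_swap)
    pick <- sample(swappable, n_swap + n_strand)
    i_swap <- pick[seq_len(n_swap)]
    i_strand <- pick[n_swap + seq_len(n_strand)]
    if (n_swap > 0) {
      ea <- score_a$effect_allele[i_swap]
      score_a$effect_allele[i_swap] <- score_a$other_allele[i_swap]
      score_a$other_allele[i_swap] <- ea
      score_a$weight[i_swap] <- -score_a$weight[i_swap]
    }
    if (n_strand > 0) {
      score_a$effect_allele[i_strand] <-
        complement_allele(score_a$effect_allele[i_strand])
      score_a$other_allele[i_strand] <-
        complement_allele(score_a$other_allele[i_strand])
    }
    attr(score_a, "planted") <- list(
      swapped = score_a$variant_id[i_swap],
      strand_flipped = score_a$variant_id[i_strand]
    )
    list(score_a = score_a, score_b = score_b)
  })
}

#' Generate a cohort table with outcome, covariates and sample-QC flags
#'
#' Simulates age (uniform 40-69 years), sex, genotyping array (two platforms
#' at a 90/10 split), five standard-normal ancestry PCs, and a disease
#' outcome driven by the standardized PRS built from `scores$score_a` on the
#' panel, via either a logistic model (`outcome_mode = "binary"`) or a
#' thresholded quantitative trait (`outcome_mode = "threshold"`,
#' hypertension-style). When the logistic intercept is left `NULL` it is
#' solved by 1-D root finding so the empirical-expectation prevalence equals
#' `prevalence_target`. Sample-QC flags are planted independently at
#' `qc_flag_rates`.
#'
#' @param panel A `dosage_panel`.
#' @param scores The score pair from [generate_score_pair()].
#' @param config The same [sim_config()].
#' @return A cohort tibble (columns `sample_id`, `outcome`, `age`, `sex`,
#'   `array`, `pc1`..`pc5`, and logical QC-flag columns). The generating
#'   linear predictor and true standardized score are kept in the
#'   `"truth"` attribute for diagnostics.
#' @export
generate_cohort <- function(panel, scores, config) {
  stopifnot(inherits(config, "sim_config"), inherits(panel, "dosage_panel"))
  with_seed(sim_seed(config, "cohort"), {
    n <- config$n_individuals
    stopifnot(length(panel$sample_ids) == n)
    harmonized <- harmonize_alleles(scores$score_a, panel)$score
    prs <- standardize_prs(compute_prs(harmonized, panel))
    prs_z <- prs$standardized

    age <- runif(n, 40, 69)
    age_z <- (age - mean(age)) / sd(age)
    sex <- if (config$sex_mode == "female_only") {
      rep("female", n)
    } else {
      ifelse(runif(n) < 0.5, "female", "male")
    }
    array <- ifelse(runif(n) < 0.9, "axiom", "bileve")
    pcs <- matrix(rnorm(5L * n), ncol = 5)
    colnames(pcs) <- paste0("pc", 1:5)

    dm <- config$disease_model
    eta0 <- dm$beta_prs * prs_z + dm$beta_age * age_z +
      dm$beta_sex * (sex == "male")

    if (config$outcome_mode == "binary") {
      b0 <- dm$intercept
      if (is.null(b0)) {
        b0 <- uniroot(
          function(b) mean(plogis(b + eta0)) - config$prevalence_target,
          interval = c(-30, 10), tol = 1e-10
        )$root
      }
      outcome <- as.integer(runif(n) < plogis(b0 + eta0))
      trait <- rep(NA_real_, n)
    } else {
      trait <- config$trait_mean + config$trait_sd * eta0 +
        rnorm(n, 0, config$trait_sd)
      outcome <- as.integer(trait >= config$trait_threshold)
      b0 <- NA_real_
    }

    rates <- config$qc_flag_rates
    cohort <- tibble::tibble(
      sample_id = panel$sample_ids,
      outcome = outcome,
      age = age,
      sex = sex,
      array = array,
      pc1 = pcs[, 1], pc2 = pcs[, 2], pc3 = pcs[, 3],
      pc4 = pcs[, 4], pc5 = pcs[, 5],
      sex_discordant = runif(n) < rates[["sex_discordant"]],
      related = runif(n) < rates[["related"]],
      het_miss_outlier = runif(n) < rates[["het_miss_outlier"]]
    )
    attr(cohort, "truth") <- tibble::tibble(
      sample_id = panel$sample_ids,
      prs_true_z = prs_z,
      linear_predictor = eta0,
      intercept = b0,
      trait = trait
    )
    cohort
  })
}

#' Predicted correlation between the two generated scores
#'
#' Under the generator with `within_block_corr = 0` (independent variants),
#' the correlation of the two raw scores has the closed form
#' \deqn{\rho^* = \frac{\sum_{i \in S} \beta_i^A \beta_i^B v_i}
#'   {\sqrt{\sum_i (\beta_i^A)^2 v_i \; \sum_i (\beta_i^B)^2 v_i}}}
#' where the sum in the numerator runs over shared variants and
#' \eqn{v_i = 2 p_i (1 - p_i)} is the Hardy-Weinberg dosage variance at the
#' realized counted-allele frequency. This is the analytic value the
#' empirical Pearson correlation should recover, and is used to check
#' parameter recovery of the generator.
#'
#' @param score_a,score_b The two scoring files (as generated; planted
#'   allele swaps are accounted for by sign).
#' @param panel The generating panel.
#' @return The predicted Pearson correlation (a single number).
#' @export
expected_score_correlation <- function(score_a, score_b, panel) {
  v <- panel$variants
  freq <- rowMeans(panel$dosages) / 2
  var_d <- 2 * freq * (1 - freq)

  effective_weight <- function(score) {
    i <- match(score$variant_id, v$variant_id)
    w <- score$weight
    # entries written with effect = panel allele2 act with opposite sign on
    # the counted-allele dosage
    swapped <- score$effect_allele == v$allele2[i] |
      score$effect_allele == complement_allele(v$allele2[i])
    w[swapped] <- -w[swapped]
    setNames(w, score$variant_id)
  }
  wa <- effective_weight(score_a)
  wb <- effective_weight(score_b)
  shared <- intersect(names(wa), names(wb))
  va <- var_d[match(names(wa), v$variant_id)]
  vb <- var_d[match(names(wb), v$variant_id)]
  vs <- var_d[match(shared, v$variant_id)]
  sum(wa[shared] * wb[shared] * vs) /
    sqrt(sum(wa^2 * va) * sum(wb^2 * vb))
}

#' Latent AR(1) correlation needed for a target dosage-scale R-squared
#'
#' Hard-call dosages attenuate the latent Gaussian correlation: thresholding
#' at allele frequency `p` maps a latent correlation to a smaller
#' genotype-scale correlation (the phi coefficient of the two allele
#' indicators). This helper inverts that map numerically for equal allele
#' frequencies, so a panel can be configured to reach a desired adjacent-pair
#' dosage R-squared.
#'
#' @param target_r2 Desired squared dosage correlation of an adjacent pair.
#' @param maf Allele frequency at which both variants sit.
#' @return The latent `within_block_corr` to configure.
#' @export
latent_corr_for_dosage_r2 <- function(target_r2, maf = 0.3) {
  assert_scalar_number(target_r2, "target_r2", 0, 1, hi_open = TRUE)
  target <- sqrt(target_r2)
  uniroot(
    function(rho) dosage_corr_from_latent(rho, maf) - target,
    interval = c(0, 0.999999), tol = 1e-9
  )$root
}

# phi coefficient of two equal-frequency allele indicators thresholded from
# a bivariate normal with correlation rho; the dosage correlation equals it
# because dosages are sums of two iid haplotype indicators.
dosage_corr_from_latent <- function(rho, p) {
  if (rho == 0) return(0)
  z <- qnorm(p)
  p11 <- bvn_lower_prob(z, z, rho)
  (p11 - p^2) / (p * (1 - p))
}

# P(X < h, Y < k) for standard bivariate normal, by 1-D quadrature.
bvn_lower_prob <- function(h, k, rho) {
  integrate(
    function(x) dnorm(x) * pnorm((k - rho * x) / sqrt(1 - rho^2)),
    -Inf, h, rel.tol = 1e-10
  )$value
}
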