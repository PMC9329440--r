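# Hand-built micro fixtures and a lazily-built, cached simulated study so
# expensive generation runs at most once per test session.

tiny_panel <- function(dosages = NULL,
                       alleles = list(c("A", "G"), c("C", "T")),
                       info = NULL) {
  if (is.null(dosages)) {
    dosages <- matrix(c(0, 1, 2,
                        2, 1, 0), nrow = 2, byrow = TRUE)
  }
  nv <- nrow(dosages)
  a1 <- vapply(seq_len(nv), function(i) alleles[[((i - 1) %% length(alleles)) + 1]][1], "")
  a2 <- vapply(seq_len(nv), function(i) alleles[[((i - 1) %% length(alleles)) + 1]][2], "")
  dosage_panel(
    tibble::tibble(
      variant_id = paste0("rs", seq_len(nv)),
      chromosome = "1",
      position = seq_len(nv) * 1000L,
      allele1 = a1,
      allele2 = a2,
      info_score = info %||% rep(0.99, nv)
    ),
    dosages,
    sample_ids = paste0("s", seq_len(ncol(dosages)))
  )
}

tiny_score <- function(panel, weights, effect = NULL, other = NULL,
                       id = "PRS-T") {
  v <- panel$variants[seq_along(weights), ]
  score_file(
    tibble::tibble(
      variant_id = v$variant_id,
      chromosome = v$chromosome,
      position = v$position,
      effect_allele = effect %||% v$allele1,
      other_allele = other %||% v$allele2,
      weight = weights
    ),
    score_id = id
  )
}

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Mid-sized study used by several integration tests: independent variants
# (no LD) so closed-form expectations hold.
study_no_ld <- function() {
  cached_fixture("study_no_ld", function() {
    cfg <- sim_config(
      n_individuals = 8000, n_blocks = 30, block_size = 10,
      within_block_corr = 0, maf_range = c(0.1, 0.5),
      n_snps_a = 120, n_snps_b = 120, shared_fraction = 0.72,
      weight_corr = 0.8, prevalence_target = 0.08, seed = 42
    )
    panel <- generate_panel(cfg)
    scores <- generate_score_pair(panel, cfg)
    cohort <- generate_cohort(panel, scores, cfg)
    list(cfg = cfg, panel = panel, scores = scores, cohort = cohort)
  })
}

random_panel_scores <- function(n_var = 50, n_ind = 200, seed = 99) {
  set.seed(seed)
  dos <- matrix(sample(0:2, n_var * n_ind, replace = TRUE), nrow = n_var) * 1.0
  panel <- tiny_panel(dos)
  w <- rnorm(n_var, 0, 0.2)
  list(panel = panel, score = tiny_score(panel, w))
}
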