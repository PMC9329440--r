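---
title: "Methods: measuring agreement between polygenic risk scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring agreement between polygenic risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsconcord)
```

## The problem

A polygenic risk score (PRS) for individual $j$ is the weighted allele
count
$$\mathrm{PRS}_j = \sum_i \beta_i \, d_{ij},$$
with $\beta_i$ the published per-effect-allele weight of SNP $i$ and
$d_{ij} \in [0,2]$ the imputed effect-allele dosage. For most diseases
several published scores coexist, built from overlapping GWAS data with
different variant-selection and shrinkage strategies. Two such scores can
be nearly indistinguishable by population-level discrimination (AUC) yet
assign many individuals to very different risk percentiles. `prsconcord`
quantifies that individual-level disagreement.

The unit of analysis is always a *pair* of scores evaluated on one cohort:
the package computes both scores per individual, ranks each score within
the analysis population, and measures agreement on the continuous scale
(Pearson $r$), on the percentile scale (cross-classification, top-$k$\%
concordance) and on the clinical-modelling scale (odds ratios, AUC, net
reclassification).

## Pipeline and its assumptions

`run_prs_agreement()` executes the stages in a fixed order:

1. **Sample QC** — individuals carrying any of the flags
   `sex_discordant`, `related`, `het_miss_outlier` are removed. The flags
   are consumed, not derived; they represent upstream genotyping QC of the
   kind large biobanks distribute.
2. **Variant QC** (`apply_variant_qc()`) — per scoring file, against the
   post-sample-QC panel: variants absent from the panel; palindromic (A/T,
   C/G) variants with minor allele frequency above 0.49; variants with MAF
   below 0.005; variants whose imputation info score is not strictly above
   0.4. Precedence is unmatched > ambiguous > rare > low-info, each variant
   counted once; the operation is idempotent.
3. **Allele harmonization** (`harmonize_alleles()`) — the published
   effect/other alleles are matched to the panel's allele pair, in either
   order, with strand complements resolved for non-palindromic pairs only.
4. **Scoring** (`compute_prs()`, `standardize_prs()`, `assign_bins()`).
5. **Variant overlap** (`ld_overlap()`) and the **agreement report**
   (`concordance_report()`).

Assumptions worth making explicit:

- *MAF source.* The MAF used by the QC rules is computed in the target
  panel (after sample QC), not in an external reference: target dosages
  are the only frequencies guaranteed to be available, and the ambiguity
  rule is about resolvability in the data actually being scored.
- *Harmonization direction.* When the effect allele is the panel's
  non-counted allele, the dosage is complemented ($2-d$) and the published
  weight kept, rather than negating the weight. The two are identical up
  to the additive constant $2\beta$, which standardization removes; the
  complement form leaves score files byte-identical to what was published.
- *Risk orientation.* Higher score = higher risk is assumed for both
  scores; no automatic sign alignment is attempted.
- *Percentiles.* Ranks use the convention
  $100 (\mathrm{rank} - 0.5)/N$ with average ranks on ties. This makes the
  top-$k$\% group contain exactly $Nk/100$ individuals for distinct
  values, puts an all-tied sample at percentile 50 (bin 40–60), and makes
  bin occupancy follow the $(1, 19, 20, 20, 20, 19, 1)$\% law. Ranking is
  done in the full analysis population, not among controls.
- *Bins.* The seven categories $<1$, 1–20, 20–40, 40–60, 60–80, 80–99,
  $\ge 99$ are half-open $[\mathrm{lo}, \mathrm{hi})$ with the top bin
  closed above, so "$\ge 99$" is the top 1\% of the distribution.

## The agreement statistics

- **Cross-classification** (`cross_classify()`): counts by (bin under A,
  bin under B) with row, column and cell percentages, each rounded half
  away from zero to one decimal — the convention of published
  reclassification tables (base `round()` rounds half to even and would
  print 23.0 where the table shows 23.1). `render_crosstab()` prints each
  cell as `n (row%, col%, cell%)`, the layout such tables are published
  in.
- **Top-$k$\% concordance** (`topk_concordance()`): the fraction of A's
  top-$k$\% group also in B's. Symmetric in the two scores except for
  ties at the cut.
- **Odds ratios** (`or_at_cutpoints()`): logistic model of the outcome on
  a top-$k$ indicator versus the middle quintile (percentiles 40–60),
  adjusted for age, sex, genotyping array and five ancestry PCs; sex and
  array drop out automatically when constant (e.g. single-sex
  populations). Wald 95\% intervals. An empty-case reference group is an
  explicit error, not an infinite estimate.
- **AUC** (`auc_mann_whitney()`): the rank-based Mann–Whitney estimator
  with ties counting one half, applied to fitted probabilities from a
  "crude" model (score + array + PCs) and a "multivariable" model (plus
  age and sex).
- **NRI**: continuous
  ($\mathrm{up} \equiv p_\mathrm{new} > p_\mathrm{old}$, exact ties
  contribute zero — Pencina's convention) and categorical (movement across
  the seven percentile bins), with score B's model as the update.
- **Bootstrap** (`bootstrap_ci()`): percentile intervals at 2.5/97.5 from
  1,000 replications by default, resampling individuals with replacement
  under a fixed seed. For AUC and NRI the resampling is over the fitted
  risks and outcomes *without refitting the models* in each replicate;
  this measures evaluation-set uncertainty at fixed models and keeps a
  1,000-replicate report tractable, but mildly understates the
  model-refitting component of the variance. BCa corrections were judged
  unnecessary for these near-symmetric statistics.

## The Gaussian tail-concordance oracle

If two standardized scores were jointly Gaussian with correlation $\rho$,
the expected top-$k$\% concordance has the closed form
$$C(\rho, k) = \frac{1}{k/100} \int_z^\infty \phi(x)\,
  \bar\Phi\!\left(\frac{z - \rho x}{\sqrt{1 - \rho^2}}\right) dx,
  \qquad z = \Phi^{-1}(1 - k/100),$$
implemented by adaptive quadrature (absolute tolerance $10^{-9}$) with a
Monte Carlo cross-check. $C$ is strictly increasing in $\rho$, equals
$k/100$ at independence, and tends to 1 as $\rho \to 1$. This is both a
validation oracle for `topk_concordance()` and the explanatory layer: the
between-score correlations typically reported for PRS pairs
($r \approx 0.5$–$0.65$) imply top-1\% concordances of only
$\approx 13$–$23\%$ under joint normality — modest correlation, dramatic
individual-level reclassification. Published breast-cancer and
hypertension concordances sit close to the Gaussian prediction at their
printed correlations; scores built from a few dozen SNPs (dementia-like)
can exceed it, since a 39–57-SNP score is not well approximated by a
Gaussian copula in its extreme tail. Non-Gaussian copulas are out of
scope.

## What the generator simulates

`sim_config()` + `generate_panel()`/`generate_score_pair()`/
`generate_cohort()` produce a complete synthetic study. Choices, with
defaults and reasons:

- **Cohort size** `n_individuals = 20000`: large enough that the 1\% tail
  bins hold 200 individuals and rank statistics are stable, small enough
  that a full pipeline run takes seconds.
- **LD structure**: `n_blocks = 50` blocks of `block_size = 10` variants.
  Each block draws, per haplotype, a latent Gaussian vector with AR(1)
  correlation `within_block_corr` (default 0.9); the allele indicator is
  the latent falling below $\Phi^{-1}(p)$ at the variant's frequency
  $p \sim U(\texttt{maf\_range})$, and the genotype is the sum of two
  independent haplotypes. This yields exact Hardy–Weinberg marginals
  ($E[d] = 2p$), LD decaying with distance inside a block, and
  independence across blocks. Blocks sit 2 Mb apart on a chromosome
  (beyond the 500 kb proxy window); variants within a block are 5 kb
  apart.
- **Attenuation**: thresholding attenuates correlation, so the dosage-scale
  $R^2$ of an adjacent pair is the squared phi coefficient of the two
  indicators — about 0.62 at latent 0.95 and MAF 0.3, not 0.95². The
  closed-form map and its numerical inverse are exported
  (`latent_corr_for_dosage_r2()`); fixtures that need $R^2 > 0.8$ proxies
  configure the latent correlation through it (≈ 0.99) rather than
  guessing.
- **Scores**: weights are $N(0, 0.1^2)$ (the scale cancels under
  standardization); score B shares `round(shared_fraction · n_snps_a)` of
  A's variants with weights correlated at `weight_corr`, exactly equal
  when `weight_corr = 1`. Under independent variants the induced score
  correlation has the closed form implemented in
  `expected_score_correlation()` (shared-variance algebra with
  $v_i = 2p_i(1-p_i)$), which the generator is required to recover
  empirically within ±0.02 at $n = 20{,}000$.
- **Planted defects**: configurable numbers of palindromic variants at
  frequency 0.5, rare variants at MAF 0.002, low-info variants
  (info ∈ (0.30, 0.40]), allele-order swaps (effect/other exchanged with
  negated weight) and strand flips, so QC and harmonization have exact,
  known work to do. Ordinary variants always receive non-palindromic
  allele pairs so the ambiguity rule fires only where planted.
- **Disease model**: logistic on the standardized score from file A plus
  standardized age and a male indicator
  (`beta_prs = 0.5`, `beta_age = 0.3`, `beta_sex = 0.2` on the log-odds
  scale — effect sizes in the range reported for common-disease PRS). The
  intercept is solved by 1-D root finding (`uniroot`, tolerance
  $10^{-10}$) so the cohort's expected prevalence equals
  `prevalence_target` (default 0.05, a cancer-like incident fraction).
  A threshold mode instead simulates a blood-pressure-like trait (mean
  138, residual sd 15 mmHg) and defines the outcome as trait ≥ 140,
  mimicking hypertension defined from a baseline measurement.
- **Sample-QC flags** at rates 0.002 / 0.03 / 0.005
  (sex-discordant / related / het-miss outlier) — relatedness dominating,
  as in real cohorts.
- **Seeds**: one master seed; panel, scores and cohort use fixed
  sub-streams (master + 1, 2, 3), each generated under a local RNG state
  so the caller's stream is never perturbed. Identical configuration ⇒
  bit-identical study.

What the generator does **not** emulate: realistic human LD maps and
recombination hotspots, ancestry admixture and PC–genotype correlation
(PCs are independent noise), genotyping error, X-chromosome dosages,
non-integer imputed dosages by default (a uniform-noise option exists),
and any relationship between info scores and the dosages themselves (info
is simulated metadata; the pipeline only thresholds it). Tests passing on
this generator therefore establish the *statistical machinery* —
QC counting, harmonization algebra, ranking, model fitting, the
concordance/NRI estimators — not robustness to real-data pathologies such
as build mismatches or systematically mis-stranded reference panels.

## Numerical choices and degenerate inputs

- Logistic fits run IRLS (via `stats::glm`) with tolerance $10^{-10}$ and
  up to 100 iterations; non-convergence or separation (detected by
  exploding coefficients with huge standard errors) raises an error rather
  than returning Wald statistics that mean nothing.
- Zero retained scoring variants, constant scores (zero variance),
  single-class outcomes, empty panels and empty middle-quintile case
  groups are all explicit errors with named causes.
- Monomorphic variants have undefined LD; `dosage_r2()` returns `NA` and
  the overlap stage counts the variant unmatched.
- Proxy ties on best $R^2$ break by smallest base-pair distance, then
  lexicographic variant id — determinism over floating-point
  coincidences.
- Percentages round half away from zero with a $10^{-9}$ guard so decimal
  ties that sit a hair below .5 in binary still round up.
- Variant matching uses `variant_id` as the primary key with a
  chromosome:position fallback; coordinates are 1-based.

## Problem sizes in the test suite

The suite validates rank-statistics and generator calibration at
$n = 20{,}000$ individuals (the size at which 1\% tails hold 200 people),
runs integration fixtures at $n = 1{,}200$–$8{,}000$, estimates the
Gaussian-copula concordances at $n = 2 \times 10^6$ simulated pairs
(Monte Carlo error ≈ 0.3 pp on the top-1\% estimate), and checks null OR
coverage over 100 replicate cohorts of $n = 10{,}000$. The published
reclassification-table recomputation is exact arithmetic on its 49 printed
counts.

## Known limitations

- Percentile-bootstrap, fixed-model CIs (see above); refitting bootstrap
  or analytic (DeLong) AUC intervals are not implemented.
- The LD proxy search is within ±500 kb on the same chromosome against
  the analysis panel itself; no external reference panel support.
- VCF/BGEN dosage input is not parsed; the tab-separated panel format (or
  an in-memory `dosage_panel`) is the adapter point.
- No Cox/survival modelling of incident disease, no calibration
  statistics, no sample-overlap correction between score derivation and
  evaluation cohorts.
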