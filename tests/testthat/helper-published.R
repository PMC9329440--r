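# Published 7x7 cross-classification of breast-cancer risk percentiles under
# two PRS in a cohort of 171,490 women: counts and the percentages exactly as
# printed (each cell "n (row%, col%, cell%)", one decimal). Rows are bins of
# the earlier score, columns of the later score, in the order
# <1, 1-20, 20-40, 40-60, 60-80, 80-99, >=99.

published_crosstab_counts <- function() {
  m <- matrix(c(
      345,  1140,  176,   44,    9,     1,    0,
     1117, 15409, 8818, 4696, 2052,   490,    1,
      198,  8788, 9989, 8053, 5210,  2051,    9,
       43,  4648, 7998, 8908, 8050,  4607,   44,
       11,  2098, 5296, 7988, 10047, 8688,  170,
        1,   497, 2006, 4574, 8736, 15674, 1095,
        0,     3,   15,   35,  194,  1072,  396
  ), nrow = 7, byrow = TRUE)
  bins <- c("<1", "1-20", "20-40", "40-60", "60-80", "80-99", ">=99")
  dimnames(m) <- list(a_bin = bins, b_bin = bins)
  m
}

published_crosstab_row_pct <- function() {
  matrix(c(
    20.1, 66.5, 10.3,  2.6,  0.5,  0.1,  0.0,
     3.4, 47.3, 27.1, 14.4,  6.3,  1.5,  0.0,
     0.6, 25.6, 29.1, 23.5, 15.2,  6.0,  0.0,
     0.1, 13.6, 23.3, 26.0, 23.5, 13.4,  0.1,
     0.0,  6.1, 15.4, 23.3, 29.3, 25.3,  0.5,
     0.0,  1.5,  6.2, 14.0, 26.8, 48.1,  3.4,
     0.0,  0.2,  0.9,  2.0, 11.3, 62.5, 23.1
  ), nrow = 7, byrow = TRUE, dimnames = dimnames(published_crosstab_counts()))
}

published_crosstab_col_pct <- function() {
  matrix(c(
    20.1,  3.5,  0.5,  0.1,  0.0,  0.0,  0.0,
    65.1, 47.3, 25.7, 13.7,  6.0,  1.5,  0.1,
    11.5, 27.0, 29.1, 23.5, 15.2,  6.3,  0.5,
     2.5, 14.3, 23.3, 26.0, 23.5, 14.1,  2.6,
     0.6,  6.4, 15.4, 23.3, 29.3, 26.7,  9.9,
     0.1,  1.5,  5.8, 13.3, 25.5, 48.1, 63.8,
     0.0,  0.0,  0.0,  0.1,  0.6,  3.3, 23.1
  ), nrow = 7, byrow = TRUE, dimnames = dimnames(published_crosstab_counts()))
}

published_crosstab_cell_pct <- function() {
  matrix(c(
    0.2, 0.7, 0.1, 0.0, 0.0, 0.0, 0.0,
    0.7, 9.0, 5.1, 2.7, 1.2, 0.3, 0.0,
    0.1, 5.1, 5.8, 4.7, 3.0, 1.2, 0.0,
    0.0, 2.7, 4.7, 5.2, 4.7, 2.7, 0.0,
    0.0, 1.2, 3.1, 4.7, 5.9, 5.1, 0.1,
    0.0, 0.3, 1.2, 2.7, 5.1, 9.1, 0.6,
    0.0, 0.0, 0.0, 0.0, 0.1, 0.6, 0.2
  ), nrow = 7, byrow = TRUE, dimnames = dimnames(published_crosstab_counts()))
}

# Published between-score Pearson correlations for the three disease pairs.
published_correlations <- function() {
  c(breast_cancer = 0.65, hypertension = 0.66, dementia = 0.51)
}
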