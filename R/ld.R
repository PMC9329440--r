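#' Squared dosage correlation between two panel variants
#'
#' The composite-LD estimator on unphased dosages: the squared Pearson
#' correlation of the two dosage vectors. Returns `NA` when either variant
#' is monomorphic (undefined; treated as no proxy by [ld_overlap()]).
#'
#' @param panel A [dosage_panel()].
#' @param variant_x,variant_y Variant ids.
#' @return A single value in `[0, 1]`, or `NA`.
#' @export
dosage_r2 <- function(panel, variant_x, variant_y) {
  stopifnot(inherits(panel, "dosage_panel"))
  i <- match(c(variant_x, variant_y), panel$variants$variant_id)
  if (anyNA(i)) {
    abort(sprintf("variant(s) not in panel: %s",
                  paste(c(variant_x, variant_y)[is.na(i)], collapse = ", ")))
  }
  x <- panel$dosages[i[1], ]
  y <- panel$dosages[i[2], ]
  if (var(x) == 0 || var(y) == 0) return(NA_real_)
  cor(x, y)^2
}

#' Variant overlap between two scores, counting LD proxies
#'
#' For each variant of score A: a direct match if score B carries the same
#' variant (by id, falling back to chromosome:position); otherwise a proxy
#' match if some score-B variant on the same chromosome within
#' `window` base pairs has squared dosage correlation strictly greater
#' than `r2_threshold` in the panel; otherwise unmatched. Ties on the best
#' R-squared are broken by smallest base-pair distance, then lexicographic
#' variant id, so results are deterministic. Score-A variants absent from
#' the panel (and not directly matched) are counted unmatched.
#'
#' @param score_a,score_b Two [score_file()] objects.
#' @param panel The [dosage_panel()] on which LD is estimated.
#' @param r2_threshold Proxy threshold (strict; default 0.8).
#' @param window Proxy search window in base pairs on each side
#'   (default 500 kb).
#' @return A list of class `ld_overlap` with counts `n_direct`, `n_proxy`,
#'   `n_unmatched`, the `overlap_fraction`
#'   `(n_direct + n_proxy) / nrow(score_a)`, and a `pairs` tibble
#'   (`variant_a`, `variant_b`, `match_type`, `r2`, `distance`).
#' @export
ld_overlap <- function(score_a, score_b, panel, r2_threshold = 0.8,
                       window = 500000) {
  stopifnot(inherits(score_a, "score_file"), inherits(score_b, "score_file"),
            inherits(panel, "dosage_panel"))
  assert_scalar_number(r2_threshold, "r2_threshold", 0, 1)
  pv <- panel$variants
  key_b_id <- score_b$variant_id
  key_b_pos <- paste(score_b$chromosome, score_b$position, sep = ":")
  b_panel_row <- match_to_panel(score_b, panel)

  n_a <- nrow(score_a)
  match_type <- character(n_a)
  best_b <- rep(NA_character_, n_a)
  best_r2 <- rep(NA_real_, n_a)
  best_dist <- rep(NA_real_, n_a)
  a_panel_row <- match_to_panel(score_a, panel)

  for (idx in seq_len(n_a)) {
    id <- score_a$variant_id[idx]
    pos_key <- paste(score_a$chromosome[idx], score_a$position[idx],
                     sep = ":")
    j <- which(key_b_id == id | key_b_pos == pos_key)
    if (length(j)) {
      match_type[idx] <- "direct"
      best_b[idx] <- key_b_id[min(j)]
      next
    }
    if (is.na(a_panel_row[idx])) {
      match_type[idx] <- "unmatched"
      next
    }
    row_a <- a_panel_row[idx]
    cand <- which(!is.na(b_panel_row) &
                    pv$chromosome[b_panel_row] == pv$chromosome[row_a] &
                    abs(pv$position[b_panel_row] - pv$position[row_a]) <=
                      window)
    if (!length(cand)) {
      match_type[idx] <- "unmatched"
      next
    }
    x <- panel$dosages[row_a, ]
    if (var(x) == 0) {
      match_type[idx] <- "unmatched"
      next
    }
    r2 <- vapply(cand, function(jj) {
      y <- panel$dosages[b_panel_row[jj], ]
      if (var(y) == 0) NA_real_ else cor(x, y)^2
    }, numeric(1))
    dist <- abs(pv$position[b_panel_row[cand]] - pv$position[row_a])
    ok <- which(!is.na(r2) & r2 > r2_threshold)
    if (!length(ok)) {
      match_type[idx] <- "unmatched"
      next
    }
    ord <- ok[order(-r2[ok], dist[ok], key_b_id[cand[ok]])]
    pick <- ord[1]
    match_type[idx] <- "proxy"
    best_b[idx] <- key_b_id[cand[pick]]
    best_r2[idx] <- r2[pick]
    best_dist[idx] <- dist[pick]
  }

  pairs <- tibble::tibble(
    variant_a = score_a$variant_id,
    variant_b = best_b,
    match_type = match_type,
    r2 = best_r2,
    distance = best_dist
  )
  structure(
    list(
      pairs = pairs,
      n_direct = sum(match_type == "direct"),
      n_proxy = sum(match_type == "proxy"),
      n_unmatched = sum(match_type == "unmatched"),
      n_score_a = n_a,
      overlap_fraction = sum(match_type != "unmatched") / n_a,
      r2_threshold = r2_threshold,
      window = window
    ),
    class = "ld_overlap"
  )
}

#' @export
print.ld_overlap <- function(x, ...) {
  cat(sprintf(
    "<ld_overlap> %d direct + %d proxy of %d score-A variants (%.1f%%); %d unmatched\n",
    x$n_direct, x$n_proxy, x$n_score_a, 100 * x$overlap_fraction,
    x$n_unmatched
  ))
  cat(sprintf("  proxy rule: R^2 > %g within %s bp\n", x$r2_threshold,
              format(x$window, big.mark = ",")))
  invisible(x)
}

#' @export
tidy.ld_overlap <- function(x, ...) {
  x$pairs
}

#' @export
glance.ld_overlap <- function(x, ...) {
  tibble::tibble(
    n_direct = x$n_direct, n_proxy = x$n_proxy,
    n_unmatched = x$n_unmatched, n_score_a = x$n_score_a,
    overlap_fraction = x$overlap_fraction,
    r2_threshold = x$r2_threshold, window = x$window
  )
}
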