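# Internal helpers shared across modules.

# Round half away from zero to `digits` decimals. base::round() rounds half
# to even, which does not match how published risk tables are typically
# formatted (e.g. 23.05 -> 23.1).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # the 1e-9 guard keeps values that are exact .5 ties in decimal (but sit
  # a hair below in binary) rounding upward
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so seeded helpers do not perturb global
# reproducibility. `seed = NULL` leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

DNA_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

complement_allele <- function(x) {
  unname(DNA_COMPLEMENT[x])
}

# A/T and C/G pairs cannot be strand-resolved from alleles alone.
is_palindromic <- function(a1, a2) {
  a1 == complement_allele(a2)
}

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf,
                                 lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    abort(sprintf(
      "`%s` must be a single finite number in %s%s, %s%s (got %s)",
      name, if (lo_open) "(" else "[", format(lo), format(hi),
      if (hi_open) ")" else "]",
      paste(format(x), collapse = ", ")
    ))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x == as.integer(x) && x >= min
  if (!ok) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  invisible(as.integer(x))
}
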