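# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never disturb
# the user's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive `n` reproducible sub-seeds (< 2^31) from a master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

assert_scalar_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

# Runs of TRUE in a logical vector -> tibble(start, length).
na_runs <- function(is_na) {
  r <- rle(is_na)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble::tibble(start = starts[r$values], length = r$lengths[r$values])
}
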