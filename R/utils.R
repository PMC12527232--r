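# Internal helpers: argument checks and seed management.

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || (strict_lower && x <= lower) || x > upper) {
    abort(sprintf(
      "`%s` must be in %s%s, %s]; got %g.",
      name, if (strict_lower) "(" else "[", format(lower), format(upper), x
    ))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != as.integer(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

assert_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf(
      "`%s` is missing required column(s): %s.",
      name, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Deterministic child-seed derivation: one root seed fans out into
# independent named streams, so e.g. adding procedures never perturbs the
# zip-area draws. Streams are ordered draws from a generator seeded at root.
child_seeds <- function(seed, streams) {
  seed <- assert_count(seed, "seed", min = 0L)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  draws <- sample.int(.Machine$integer.max - 1L, length(streams))
  setNames(as.integer(draws), streams)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

zero_pad_ids <- function(prefix, n) {
  sprintf(paste0(prefix, "%0", max(1L, nchar(as.character(n))), "d"), seq_len(n))
}
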