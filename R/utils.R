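# internal argument checks ---------------------------------------------------

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

assert_count <- function(x, name, min = 1L) {
  assert_that(
    is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == trunc(x),
    sprintf("`%s` must be a single integer >= %d", name, min)
  )
}

assert_fraction <- function(x, name) {
  assert_that(
    is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1,
    sprintf("`%s` must be a single value in [0, 1]", name)
  )
}

assert_positive <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > 0 else x >= 0)
  assert_that(ok, sprintf(
    "`%s` must be a single %s number", name, if (strict) "positive" else "non-negative"
  ))
}

# derive a stage seed from a global seed; keeps values inside 32-bit range
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

# run `expr` under `seed` without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
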