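# MCMC convergence diagnostics: split R-hat and effective sample size.
# Hand-implemented (the environment ships no coda/posterior); formulas are the
# standard split-chain potential scale reduction and the initial-positive-
# sequence autocorrelation-sum ESS.

# draws: iterations x chains matrix
split_rhat <- function(draws) {
  n <- nrow(draws)
  if (n < 4L) return(NA_real_)
  half <- n %/% 2L
  splits <- cbind(draws[seq_len(half), , drop = FALSE],
                  draws[(n - half + 1L):n, , drop = FALSE])
  m <- ncol(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2L, var)
  w <- mean(vars)
  b <- half * var(means)
  if (w < 1e-12) return(1) # degenerate (constant) chains
  sqrt(((half - 1) / half * w + b / half) / w)
}

ess_chains <- function(draws) {
  n <- nrow(draws)
  m <- ncol(draws)
  if (n < 4L) return(NA_real_)
  rho_sum <- 0
  for (ch in seq_len(m)) {
    x <- draws[, ch]
    if (var(x) < 1e-12) next
    ac <- acf(x, lag.max = min(n - 2L, 200L), plot = FALSE)$acf[-1]
    # Geyer: truncate at the first non-positive sum of adjacent pairs
    s <- 0
    for (k in seq(1L, length(ac) - 1L, by = 2L)) {
      pair <- ac[k] + ac[k + 1L]
      if (pair <= 0) break
      s <- s + pair
    }
    rho_sum <- rho_sum + s
  }
  n * m / (1 + 2 * rho_sum / m)
}
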