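# Independent oracles used by the tests; kept deliberately naive and separate
# from the package's own code paths.

# Binomial pmf by multiplicative recursion (no dbinom): P(s+1)/P(s) ratio
oracle_binom_pmf <- function(total, prob) {
  pmf <- numeric(total + 1)
  pmf[1] <- (1 - prob)^total
  r <- prob / (1 - prob)
  for (s in 0:(total - 1)) {
    pmf[s + 2] <- pmf[s + 1] * (total - s) / (s + 1) * r
  }
  pmf
}

# brute-force two-sided conditional p: sum of outcomes no more probable than
# the observed male sum
oracle_exact_p <- function(s_m, total, lib_f, lib_m) {
  pmf <- oracle_binom_pmf(total, sum(lib_m) / (sum(lib_m) + sum(lib_f)))
  sum(pmf[pmf <= pmf[s_m + 1] * (1 + 1e-12)])
}

# dense-grid posterior for a one-locus, fixed-parental cline model:
# parameters (h_1..h_N, alpha, beta), uniform h prior, normal cline priors
oracle_grid_posterior <- function(G, p0, p1, prior_sd, truncation = 1e-6,
                                  n_h = 41, n_ab = 41, ab_range = 1.2) {
  stopifnot(length(G) <= 3)
  hs <- seq(0.001, 0.999, length.out = n_h)
  as <- seq(-ab_range, ab_range, length.out = n_ab)
  bs <- as
  dims <- c(rep(list(hs), length(G)), list(as), list(bs))
  grid <- do.call(expand.grid, dims)
  names(grid) <- c(paste0("h", seq_along(G)), "alpha", "beta")
  ll <- dnorm(grid$alpha, 0, prior_sd, log = TRUE) +
    dnorm(grid$beta, 0, prior_sd, log = TRUE)
  for (i in seq_along(G)) {
    phi <- cline_phi(grid[[paste0("h", i)]], grid$alpha, grid$beta, truncation)
    q <- pmin(pmax(phi * p1 + (1 - phi) * p0, 1e-12), 1 - 1e-12)
    ll <- ll + dbinom(G[i], 2, q, log = TRUE)
  }
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  vapply(names(grid), function(nm) sum(w * grid[[nm]]), numeric(1))
}

# build a variant_panel directly in code (no VCF round trip)
make_panel <- function(gt, populations, contigs = NULL, dp = NULL,
                       ad_ref = NULL, ad_alt = NULL, linkage = NA_character_) {
  L <- nrow(gt)
  contigs <- contigs %||% sprintf("c%04d", seq_len(L))
  loci <- tibble::tibble(
    locus_id = sprintf("L%04d", seq_len(L)), contig = contigs,
    pos = seq_len(L) * 10L, ref = "A", alt = "T",
    biallelic = TRUE, linkage = linkage
  )
  samples <- tibble::tibble(
    sample_id = colnames(gt) %||% sprintf("S%03d", seq_len(ncol(gt))),
    population = populations, sex = "F"
  )
  colnames(gt) <- samples$sample_id
  rownames(gt) <- loci$locus_id
  structure(list(
    loci = loci, gt = gt,
    dp = dp %||% matrix(20, L, ncol(gt), dimnames = dimnames(gt)),
    ad_ref = ad_ref, ad_alt = ad_alt,
    samples = samples, log = character()
  ), class = "variant_panel")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
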