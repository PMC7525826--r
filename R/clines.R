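#' Genomic cline function
#'
#' Probability that a gene copy in an admixed individual of hybrid index `h`
#' derives from parental population 1, as a function of the per-locus cline
#' parameters: `alpha` shifts the cline centre (direction of introgression;
#' `alpha > 0` means excess population-1 ancestry) and `beta` changes its rate
#' (amount of introgression; `beta > 0` means reduced introgression relative to
#' genome-wide expectation). The form is
#' `phi = h + 2 h (1 - h) (alpha + beta (2 h - 1))`, truncated into
#' `[truncation, 1 - truncation]` so likelihoods stay finite for extreme
#' parameter values. At `alpha = beta = 0` the cline is the identity `phi = h`.
#'
#' @param h Hybrid index (or vector), in `[0, 1]`.
#' @param alpha,beta Cline parameters (recycled against `h`).
#' @param truncation Truncation bound in `[0, 0.5)`.
#' @return `phi`, same length as the recycled inputs.
#' @examples
#' cline_phi(0.5, 0.4, 0) # 0.7
#' @export
cline_phi <- function(h, alpha, beta, truncation = 1e-6) {
  assert_that(all(is.finite(h)) && all(h >= 0 & h <= 1),
              "`h` must lie in [0, 1]")
  assert_that(truncation >= 0 && truncation < 0.5,
              "`truncation` must lie in [0, 0.5)")
  phi <- h + 2 * h * (1 - h) * (alpha + beta * (2 * h - 1))
  pmin(pmax(phi, truncation), 1 - truncation)
}

#' Genotype log-likelihood under the cline model
#'
#' Reference (pure-R) implementation of the two observation models used by the
#' MCMC. In `"known"` mode the genotype `g` (alt-allele copies) is
#' `Binomial(2, q)` with `q = phi * p1 + (1 - phi) * p0`. In `"read_counts"`
#' mode (the genotype-uncertainty model) the genotype is latent: the likelihood
#' sums over `g` of the binomial genotype prior times a binomial read layer
#' with per-read alternate probability `(g/2)(1 - e) + (1 - g/2) e` for
#' sequencing error `e`. With zero reads the read layer is constant and the
#' likelihood is 1 (prior only).
#'
#' @param g Genotype in `{0, 1, 2}` (known mode; vectorised).
#' @param alt,depth Alternate-read and total-read counts (read-count mode).
#' @param phi Ancestry probability from [cline_phi()].
#' @param p0,p1 Parental allele frequencies in `[0, 1]`.
#' @param mode `"known"` or `"read_counts"`.
#' @param seq_error Per-read error rate.
#' @return Log-likelihood(s); `-Inf` only for data impossible at `q` in
#'   `{0, 1}`.
#' @export
genotype_loglik <- function(g = NULL, alt = NULL, depth = NULL, phi, p0, p1,
                            mode = c("known", "read_counts"),
                            seq_error = 0.001) {
  mode <- match.arg(mode)
  assert_that(all(p0 >= 0 & p0 <= 1) && all(p1 >= 0 & p1 <= 1),
              "`p0`, `p1` must lie in [0, 1]")
  q <- phi * p1 + (1 - phi) * p0
  if (mode == "known") {
    assert_that(all(g %in% 0:2), "`g` must be in {0, 1, 2}")
    return(dbinom(g, 2, q, log = TRUE))
  }
  assert_that(all(depth >= 0) && all(alt >= 0) && all(alt <= depth),
              "read counts must satisfy 0 <= alt <= depth")
  e <- seq_error
  lik <- dbinom(0, 2, q) * dbinom(alt, depth, e) +
    dbinom(1, 2, q) * dbinom(alt, depth, 0.5) +
    dbinom(2, 2, q) * dbinom(alt, depth, 1 - e)
  log(lik)
}

#' Configuration for the genomic cline MCMC
#'
#' Defaults follow common practice for this model: 5 independent chains of
#' 50,000 iterations, the first 30,000 discarded as burn-in, thinning by 20
#' (1,000 retained draws per chain, 5,000 merged). `alpha` and `beta` carry
#' independent zero-mean normal priors; hybrid indices are Uniform(0, 1);
#' parental allele frequencies have Beta(1, 1) priors updated by the parental
#' allele counts and are Gibbs-resampled each sweep (set `fix_parental` to hold
#' them at their empirical values instead).
#'
#' @param n_chains Number of independent chains.
#' @param n_steps Total iterations per chain.
#' @param burn_in Iterations discarded (must be `< n_steps`).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param prior_sd_alpha,prior_sd_beta Prior standard deviations (> 0). The
#'   default 0.3 keeps three prior sd within the range where the cline is not
#'   pinned at its truncation, and regularizes a near-nonidentifiable global
#'   warp between the cline parameters and the hybrid indices that otherwise
#'   biases moderate-size panels (see the methods vignette).
#' @param phi_truncation Truncation of the cline function.
#' @param genotype_mode `"known"` or `"read_counts"`.
#' @param seq_error Per-read error rate for the genotype-uncertainty model.
#' @param ci_level Credible-interval level for outlier calls.
#' @param seed Integer seed; chain `c` runs under `seed + c - 1`.
#' @param fix_parental Hold parental allele frequencies fixed.
#' @return A `cline_config` list.
#' @export
cline_config <- function(n_chains = 5, n_steps = 50000, burn_in = 30000,
                         thin = 20, prior_sd_alpha = 0.3, prior_sd_beta = 0.3,
                         phi_truncation = 1e-6,
                         genotype_mode = c("known", "read_counts"),
                         seq_error = 0.001, ci_level = 0.95, seed = 1,
                         fix_parental = FALSE) {
  genotype_mode <- match.arg(genotype_mode)
  assert_count(n_chains, "n_chains")
  assert_count(n_steps, "n_steps")
  assert_count(burn_in, "burn_in", min = 0L)
  assert_count(thin, "thin")
  assert_that(burn_in < n_steps, "`burn_in` must be smaller than `n_steps`")
  assert_positive(prior_sd_alpha, "prior_sd_alpha")
  assert_positive(prior_sd_beta, "prior_sd_beta")
  assert_that(ci_level > 0 && ci_level < 1, "`ci_level` must lie in (0, 1)")
  structure(list(
    n_chains = n_chains, n_steps = n_steps, burn_in = burn_in, thin = thin,
    prior_sd_alpha = prior_sd_alpha, prior_sd_beta = prior_sd_beta,
    phi_truncation = phi_truncation, genotype_mode = genotype_mode,
    seq_error = seq_error, ci_level = ci_level, seed = as.integer(seed),
    fix_parental = fix_parental
  ), class = "cline_config")
}

#' Fit per-locus Bayesian genomic clines by MCMC
#'
#' Jointly samples per-admixed-individual hybrid indices, per-locus cline
#' parameters (`alpha`, `beta`) and parental allele frequencies by
#' Metropolis-within-Gibbs (see [cline_config()] for the model). Chains differ
#' only by a seed offset; proposals adapt to a 20--50% acceptance rate during
#' burn-in only, so the post-burn-in kernel is a valid fixed Metropolis kernel.
#'
#' @param panel A `variant_panel` with at least one admixed sample and one
#'   locus (see [load_variants()] / [thin_and_annotate()]).
#' @param parental Parental allele-count table from [parental_counts()]
#'   (computed from `panel` when omitted); must cover every locus.
#' @param config A [cline_config()].
#' @param parental_freqs Optional tibble `locus_id`, `p0`, `p1` used when
#'   `config$fix_parental` is `TRUE` (defaults to the empirical frequencies).
#' @return A `cline_fit` object: per-chain posterior draws of `alpha`, `beta`
#'   (loci) and `h` (admixed individuals), plus the inputs and config. Use
#'   [tidy()] for per-locus estimates and outlier calls, [hybrid_index()] for
#'   per-individual summaries, [glance()] for run-level diagnostics.
#' @export
fit_clines <- function(panel, parental = NULL, config = cline_config(),
                       parental_freqs = NULL) {
  assert_that(inherits(panel, "variant_panel"), "`panel` must be a variant_panel")
  assert_that(inherits(config, "cline_config"), "`config` must come from cline_config()")
  adm <- panel$samples$population == "admixed"
  assert_that(sum(adm) >= 1, "panel has no admixed samples")
  assert_that(nrow(panel$loci) >= 1, "panel has no loci")
  parental <- parental %||% parental_counts(panel)
  assert_that(all(panel$loci$locus_id %in% parental$locus_id),
              "parental counts must cover every locus")
  parental <- parental[match(panel$loci$locus_id, parental$locus_id), ]

  L <- nrow(panel$loci)
  G <- panel$gt[, adm, drop = FALSE]
  G[is.na(G)] <- -1L
  storage.mode(G) <- "integer"
  mode_int <- if (config$genotype_mode == "read_counts") 1L else 0L
  if (mode_int == 1L) {
    assert_that(!is.null(panel$ad_ref) && !is.null(panel$ad_alt),
                "read_counts mode needs allele depths (AD) in the panel")
    ALT <- panel$ad_alt[, adm, drop = FALSE]
    DP <- panel$ad_ref[, adm, drop = FALSE] + ALT
    ALT[is.na(ALT)] <- 0; DP[is.na(DP)] <- 0
  } else {
    ALT <- DP <- matrix(0, L, sum(adm))
  }

  if (config$fix_parental) {
    pf <- parental_freqs %||% tibble(
      locus_id = parental$locus_id,
      p0 = ifelse(parental$n0 > 0, parental$alt0 / parental$n0, 0.5),
      p1 = ifelse(parental$n1 > 0, parental$alt1 / parental$n1, 0.5)
    )
    pf <- pf[match(panel$loci$locus_id, pf$locus_id), ]
    p0_fix <- pmin(pmax(pf$p0, 1e-6), 1 - 1e-6)
    p1_fix <- pmin(pmax(pf$p1, 1e-6), 1 - 1e-6)
  } else {
    p0_fix <- p1_fix <- rep(0.5, L)
  }

  h_init <- moment_hybrid_index(G, parental)

  chains <- lapply(seq_len(config$n_chains), function(ch) {
    with_seed(config$seed + ch - 1L, {
      .cline_chain_cpp(
        G, DP, ALT, mode_int, config$seq_error,
        as.numeric(parental$alt0), as.numeric(parental$n0),
        as.numeric(parental$alt1), as.numeric(parental$n1),
        config$fix_parental, p0_fix, p1_fix,
        config$n_steps, config$burn_in, config$thin,
        config$prior_sd_alpha, config$prior_sd_beta,
        config$phi_truncation, h_init
      )
    })
  })
  structure(list(
    chains = chains,
    loci = panel$loci,
    admixed = panel$samples$sample_id[adm],
    parental = parental,
    config = config
  ), class = "cline_fit")
}

# crude moment-based starting value for h: average aligned allele dosage over
# informative loci (those whose empirical parental frequencies differ clearly)
moment_hybrid_index <- function(G, parental) {
  p0 <- ifelse(parental$n0 > 0, parental$alt0 / parental$n0, 0.5)
  p1 <- ifelse(parental$n1 > 0, parental$alt1 / parental$n1, 0.5)
  info <- abs(p1 - p0) > 0.3
  vapply(seq_len(ncol(G)), function(i) {
    g <- G[, i]
    ok <- info & g >= 0
    if (!any(ok)) return(0.5)
    dose <- ifelse(p1[ok] > p0[ok], g[ok] / 2, 1 - g[ok] / 2)
    min(max(mean(dose), 0.02), 0.98)
  }, numeric(1))
}

#' @export
print.cline_fit <- function(x, ...) {
  cat(sprintf("<cline_fit> %d loci, %d admixed individuals, %d chains x %d draws (%s mode)\n",
              nrow(x$loci), length(x$admixed), length(x$chains),
              nrow(x$chains[[1]]$alpha), x$config$genotype_mode))
  invisible(x)
}

merged_draws <- function(fit, what) {
  do.call(rbind, lapply(fit$chains, `[[`, what))
}

#' Per-locus cline estimates and credible-interval outlier calls
#'
#' Merges the thinned post-burn-in draws of all chains and reports, per locus,
#' the posterior median and mean of `alpha` and `beta`, equal-tailed credible
#' intervals at the configured level, the outlier call (`"positive"` when the
#' CI lower bound exceeds 0, `"negative"` when the upper bound is below 0,
#' `"none"` otherwise), and convergence diagnostics (split R-hat and effective
#' sample size). Loci with `rhat > 1.1` are flagged, never dropped.
#'
#' @param x A `cline_fit`.
#' @param ... Unused.
#' @return Tibble with one row per locus: `locus_id`, `linkage`, then for each
#'   parameter `<par>_med`, `<par>_mean`, `<par>_lo`, `<par>_hi`,
#'   `outlier_<par>`, `rhat_<par>`, `ess_<par>`, plus `converged`.
#' @export
tidy.cline_fit <- function(x, ...) {
  n_per_chain <- nrow(x$chains[[1]]$alpha)
  assert_that(n_per_chain >= 50,
              "insufficient posterior: fewer than 50 retained draws per chain")
  level <- x$config$ci_level
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)

  summarize_par <- function(what) {
    merged <- merged_draws(x, what)
    per_chain <- lapply(x$chains, `[[`, what)
    qs <- apply(merged, 2L, quantile, probs = probs, names = FALSE)
    tibble(
      med = apply(merged, 2L, median),
      mean = colMeans(merged),
      lo = qs[1, ], hi = qs[2, ],
      outlier = dplyr::case_when(qs[1, ] > 0 ~ "positive",
                                 qs[2, ] < 0 ~ "negative",
                                 TRUE ~ "none"),
      rhat = vapply(seq_len(ncol(merged)), function(j) {
        split_rhat(vapply(per_chain, function(m) m[, j], numeric(n_per_chain)))
      }, numeric(1)),
      ess = vapply(seq_len(ncol(merged)), function(j) {
        ess_chains(vapply(per_chain, function(m) m[, j], numeric(n_per_chain)))
      }, numeric(1))
    )
  }
  a <- summarize_par("alpha")
  b <- summarize_par("beta")
  tibble(
    locus_id = x$loci$locus_id, linkage = x$loci$linkage,
    alpha_med = a$med, alpha_mean = a$mean, alpha_lo = a$lo, alpha_hi = a$hi,
    outlier_alpha = a$outlier, rhat_alpha = a$rhat, ess_alpha = a$ess,
    beta_med = b$med, beta_mean = b$mean, beta_lo = b$lo, beta_hi = b$hi,
    outlier_beta = b$outlier, rhat_beta = b$rhat, ess_beta = b$ess,
    converged = pmax(a$rhat, b$rhat) <= 1.1
  )
}

#' Per-individual hybrid-index posterior summaries
#'
#' @param fit A `cline_fit`.
#' @return Tibble: `sample_id`, `h_med`, `h_mean`, `h_lo`, `h_hi`, `rhat_h`.
#' @export
hybrid_index <- function(fit) {
  assert_that(inherits(fit, "cline_fit"), "`fit` must be a cline_fit")
  merged <- merged_draws(fit, "h")
  n_per_chain <- nrow(fit$chains[[1]]$h)
  level <- fit$config$ci_level
  qs <- apply(merged, 2L, quantile,
              probs = c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  tibble(
    sample_id = fit$admixed,
    h_med = apply(merged, 2L, median),
    h_mean = colMeans(merged),
    h_lo = qs[1, ], h_hi = qs[2, ],
    rhat_h = vapply(seq_len(ncol(merged)), function(j) {
      split_rhat(vapply(fit$chains, function(ch) ch$h[, j], numeric(n_per_chain)))
    }, numeric(1))
  )
}

#' Run-level summary of a cline fit
#'
#' @param x A `cline_fit`.
#' @param ... Unused.
#' @return One-row tibble: dimensions, draw counts, worst R-hat, and outlier
#'   counts per parameter.
#' @export
glance.cline_fit <- function(x, ...) {
  est <- tidy(x)
  tibble(
    n_loci = nrow(est),
    n_admixed = length(x$admixed),
    n_chains = length(x$chains),
    n_draws_per_chain = nrow(x$chains[[1]]$alpha),
    max_rhat = max(est$rhat_alpha, est$rhat_beta),
    n_outlier_alpha = sum(est$outlier_alpha != "none"),
    n_outlier_beta = sum(est$outlier_beta != "none")
  )
}
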