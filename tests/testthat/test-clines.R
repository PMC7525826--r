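test_that("cline function satisfies its algebraic identities", {
  h <- seq(0, 1, length.out = 201)
  expect_equal(cline_phi(h, 0, 0, truncation = 0), h)
  expect_equal(cline_phi(0.5, 0.4, 0), 0.7)
  # mirror symmetry holds exactly before truncation
  for (i in 1:20) {
    a <- rnorm(1); b <- rnorm(1)
    expect_equal(cline_phi(1 - h, -a, b, truncation = 0),
                 1 - cline_phi(h, a, b, truncation = 0),
                 tolerance = 1e-12)
  }
  expect_error(cline_phi(1.2, 0, 0), "\\[0, 1\\]")
  # truncation keeps phi inside (0, 1) for extreme parameters
  expect_equal(cline_phi(0.5, 50, 0), 1 - 1e-6)
  expect_equal(cline_phi(0.5, -50, 0), 1e-6)
})

test_that("genotype likelihoods are correct in both observation models", {
  # certain outcome
  expect_equal(genotype_loglik(g = 2, phi = 1, p0 = 0.3, p1 = 1), 0)
  # q = 0.5 mixture: heterozygote probability 1/2
  ll <- genotype_loglik(g = 1, phi = 0.5, p0 = 0.2, p1 = 0.8)
  expect_equal(exp(ll), 0.5)
  # no reads: flat in the genotype, log-likelihood 0
  expect_equal(genotype_loglik(alt = 0, depth = 0, phi = 0.3, p0 = 0.1,
                               p1 = 0.9, mode = "read_counts"), 0)
  # read-count likelihood integrates the genotype prior
  e <- 0.01
  q <- 0.35
  manual <- log(dbinom(0, 2, q) * dbinom(3, 10, e) +
                  dbinom(1, 2, q) * dbinom(3, 10, 0.5) +
                  dbinom(2, 2, q) * dbinom(3, 10, 1 - e))
  expect_equal(genotype_loglik(alt = 3, depth = 10, phi = 0.5, p0 = 0.1,
                               p1 = 0.6, mode = "read_counts", seq_error = e),
               manual)
  expect_error(genotype_loglik(alt = 5, depth = 2, phi = 0.5, p0 = 0, p1 = 1,
                               mode = "read_counts"), "alt <= depth")
})

test_that("R and compiled likelihoods agree on random inputs", {
  set.seed(77)
  for (i in 1:50) {
    h <- runif(1); a <- rnorm(1); b <- rnorm(1)
    p0 <- runif(1, 0.01, 0.99); p1 <- runif(1, 0.01, 0.99)
    phi <- cline_phi(h, a, b)
    g <- sample(0:2, 1)
    expect_equal(
      genotype_loglik(g = g, phi = phi, p0 = p0, p1 = p1),
      xintro:::.cline_loglik_cpp(g, 0, 0, 0L, 0.001, h, a, b, 1e-6, p0, p1),
      tolerance = 1e-12
    )
    dp <- sample(0:30, 1); alt <- if (dp > 0) sample(0:dp, 1) else 0
    expect_equal(
      genotype_loglik(alt = alt, depth = dp, phi = phi, p0 = p0, p1 = p1,
                      mode = "read_counts", seq_error = 0.01),
      xintro:::.cline_loglik_cpp(-1L, dp, alt, 1L, 0.01, h, a, b, 1e-6, p0, p1),
      tolerance = 1e-10
    )
  }
})

test_that("cline config validates its invariants", {
  expect_error(cline_config(burn_in = 500, n_steps = 500), "burn_in")
  expect_error(cline_config(thin = 0), "thin")
  expect_error(cline_config(prior_sd_alpha = 0), "prior_sd_alpha")
  expect_error(cline_config(ci_level = 1), "ci_level")
  cfg <- cline_config(n_steps = 1000, burn_in = 400, thin = 3)
  expect_equal(cfg$thin, 3)
})

small_fit <- function(seed = 4, n_admixed = 25, n_loci = 30, mode = "known",
                      chains = 2, steps = 1500, burn = 700, thin = 5) {
  sim <- simulate_hybrid_zone(
    n_loci_autosomal = n_loci, n_loci_x = 0, n_parental0 = 10,
    n_parental1 = 10, n_admixed = n_admixed, allele_freq_divergence = 0.8,
    seed = seed
  )
  d <- withr::local_tempdir(.local_envir = parent.frame())
  paths <- xintro:::write_hybrid_zone(sim, d)
  panel <- load_variants(paths[["vcf"]], paths[["samples"]])
  cfg <- cline_config(n_chains = chains, n_steps = steps, burn_in = burn,
                      thin = thin, seed = seed, genotype_mode = mode)
  list(fit = fit_clines(panel, config = cfg), sim = sim, panel = panel)
}

test_that("MCMC is deterministic under a fixed seed with the stated draw count", {
  r1 <- small_fit(seed = 4)
  r2 <- small_fit(seed = 4)
  expect_identical(r1$fit$chains, r2$fit$chains)
  # retained draws per chain = floor((n_steps - burn_in) / thin)
  expect_equal(nrow(r1$fit$chains[[1]]$alpha), (1500 - 700) %/% 5)
  expect_equal(ncol(r1$fit$chains[[1]]$h), 25)
  r3 <- small_fit(seed = 5)
  expect_false(identical(r1$fit$chains, r3$fit$chains))
})

test_that("posterior summaries and outlier calls follow the CI rule", {
  draws <- 60
  mk <- function(a_shift, b_shift) {
    list(alpha = matrix(rnorm(draws * 3, rep(a_shift, each = draws), 0.01),
                        draws, 3),
         beta = matrix(rnorm(draws * 3, rep(b_shift, each = draws), 0.01),
                       draws, 3),
         h = matrix(runif(draws * 2), draws, 2))
  }
  set.seed(2)
  fake <- structure(list(
    chains = list(mk(c(1, -1, 0), c(0, 2, -2)), mk(c(1, -1, 0), c(0, 2, -2))),
    loci = tibble::tibble(locus_id = c("l1", "l2", "l3"),
                          linkage = c("X", "autosomal", "autosomal")),
    admixed = c("s1", "s2"),
    parental = NULL,
    config = cline_config(n_chains = 2, n_steps = 1000, burn_in = 400, thin = 10)
  ), class = "cline_fit")
  est <- tidy(fake)
  expect_equal(est$outlier_alpha, c("positive", "negative", "none"))
  expect_equal(est$outlier_beta, c("none", "positive", "negative"))
  expect_true(all(est$alpha_lo[est$outlier_alpha == "positive"] > 0))
  expect_true(all(est$converged))
  g <- glance(fake)
  expect_equal(g$n_outlier_alpha, 2)
  expect_equal(g$n_outlier_beta, 2)

  # insufficient retained draws per chain is an explicit error
  starved <- fake
  starved$chains <- lapply(starved$chains, function(ch) {
    lapply(ch, function(m) m[1:20, , drop = FALSE])
  })
  expect_error(tidy(starved), "insufficient posterior")
})

test_that("MCMC posterior matches a dense-grid oracle on a tiny problem", {
  # one locus, two admixed individuals, parental frequencies held fixed
  G <- matrix(c(2L, 0L), nrow = 1)
  panel <- make_panel(G, c("admixed", "admixed"))
  panel$samples <- tibble::tibble(
    sample_id = c("A1", "A2"), population = "admixed", sex = "F"
  )
  colnames(panel$gt) <- c("A1", "A2")
  parental <- tibble::tibble(locus_id = panel$loci$locus_id,
                             alt0 = 0, n0 = 0, alt1 = 0, n1 = 0)
  pf <- tibble::tibble(locus_id = panel$loci$locus_id, p0 = 0.1, p1 = 0.9)
  cfg <- cline_config(n_chains = 4, n_steps = 6000, burn_in = 2000, thin = 4,
                      seed = 12, fix_parental = TRUE)
  fit <- fit_clines(panel, parental = parental, config = cfg,
                    parental_freqs = pf)
  mcmc_means <- c(
    h1 = mean(merged <- do.call(rbind, lapply(fit$chains, `[[`, "h"))[, 1]),
    h2 = mean(do.call(rbind, lapply(fit$chains, `[[`, "h"))[, 2]),
    alpha = mean(do.call(rbind, lapply(fit$chains, `[[`, "alpha"))),
    beta = mean(do.call(rbind, lapply(fit$chains, `[[`, "beta")))
  )
  oracle <- oracle_grid_posterior(c(2L, 0L), p0 = 0.1, p1 = 0.9,
                                  prior_sd = cfg$prior_sd_alpha)
  expect_equal(unname(mcmc_means["h1"]), unname(oracle["h1"]), tolerance = 0.05)
  expect_equal(unname(mcmc_means["h2"]), unname(oracle["h2"]), tolerance = 0.05)
  expect_equal(unname(mcmc_means["alpha"]), unname(oracle["alpha"]), tolerance = 0.05)
  expect_equal(unname(mcmc_means["beta"]), unname(oracle["beta"]), tolerance = 0.05)
})

test_that("swapping parental labels mirrors the posterior", {
  sim <- simulate_hybrid_zone(
    n_loci_autosomal = 20, n_loci_x = 0, n_parental0 = 12, n_parental1 = 12,
    n_admixed = 30, allele_freq_divergence = 0.8, seed = 19
  )
  d <- withr::local_tempdir()
  paths <- xintro:::write_hybrid_zone(sim, d)
  panel <- load_variants(paths[["vcf"]], paths[["samples"]])
  cfg <- cline_config(n_chains = 2, n_steps = 3000, burn_in = 1500, thin = 5,
                      seed = 6)
  fit <- fit_clines(panel, config = cfg)

  flipped <- panel
  flipped$samples$population <- dplyr::recode(panel$samples$population,
                                              parental0 = "parental1",
                                              parental1 = "parental0")
  fit_flip <- fit_clines(flipped, config = cfg)

  est <- tidy(fit); est_flip <- tidy(fit_flip)
  expect_lt(max(abs(est_flip$alpha_med + est$alpha_med)), 0.05)
  expect_lt(max(abs(est_flip$beta_med - est$beta_med)), 0.05)
  h <- hybrid_index(fit); h_flip <- hybrid_index(fit_flip)
  expect_lt(max(abs(h_flip$h_med - (1 - h$h_med))), 0.05)
})

test_that("genotype-uncertainty mode recovers hybrid indices from read counts", {
  sim <- simulate_hybrid_zone(
    n_loci_autosomal = 60, n_loci_x = 0, n_parental0 = 12, n_parental1 = 12,
    n_admixed = 25, allele_freq_divergence = 0.9, read_depth_mean = 8,
    seq_error = 0.01, seed = 23
  )
  d <- withr::local_tempdir()
  paths <- xintro:::write_hybrid_zone(sim, d)
  panel <- load_variants(paths[["vcf"]], paths[["samples"]])
  cfg <- cline_config(n_chains = 2, n_steps = 2500, burn_in = 1200, thin = 5,
                      seed = 3, genotype_mode = "read_counts", seq_error = 0.01)
  fit <- fit_clines(panel, config = cfg)
  hi <- hybrid_index(fit)
  truth <- sim$truth$individuals
  th <- truth$h[match(hi$sample_id, truth$sample_id)]
  expect_gt(cor(hi$h_med, th), 0.9)
  expect_lt(sqrt(mean((hi$h_med - th)^2)), 0.12)
})

test_that("split R-hat and ESS behave on reference chains", {
  set.seed(30)
  iid <- matrix(rnorm(4000), 1000, 4)
  expect_lt(abs(xintro:::split_rhat(iid) - 1), 0.02)
  expect_gt(xintro:::ess_chains(iid), 2000)
  # a drifting chain among stationary ones inflates R-hat
  drift <- iid
  drift[, 1] <- drift[, 1] + seq(0, 4, length.out = 1000)
  expect_gt(xintro:::split_rhat(drift), 1.2)
})
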