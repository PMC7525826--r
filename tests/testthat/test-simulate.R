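test_that("count-matrix simulator honours its X-dosage contract", {
  # no X requested -> all autosomal truth labels
  sim0 <- simulate_count_matrix(n_contigs = 50, frac_x = 0, seed = 1)
  expect_true(all(sim0$truth$linkage == "autosomal"))

  # Poisson mode, all-X genome: pooled male:female count ratio near 1/2
  sim <- simulate_count_matrix(
    n_contigs = 10000, frac_x = 1, n_males = 1, n_females = 1,
    mean_depth = 1000, nb_dispersion = 0, seed = 42
  )
  m <- sum(sim$counts$M01)
  f <- sum(sim$counts$F01)
  expect_gt(m / f, 0.48)
  expect_lt(m / f, 0.52)

  # determinism: identical params + seed give identical output
  again <- simulate_count_matrix(
    n_contigs = 10000, frac_x = 1, n_males = 1, n_females = 1,
    mean_depth = 1000, nb_dispersion = 0, seed = 42
  )
  expect_identical(sim, again)

  expect_error(simulate_count_matrix(frac_x = 1.5), "frac_x")
  expect_error(simulate_count_matrix(n_males = 0), "n_males")
})

test_that("hybrid-zone genotypes follow the generative cline mixture", {
  # neutral clines at h = 0.5: admixed alt frequency is the parental average
  sim <- simulate_hybrid_zone(
    n_loci_autosomal = 3000, n_loci_x = 0, n_parental0 = 2, n_parental1 = 2,
    n_admixed = 40, hybrid_index = 0.5, allele_freq_divergence = 0.4, seed = 7
  )
  adm <- sim$samples$population == "admixed"
  freq <- rowMeans(sim$genotypes[, adm]) / 2
  expected <- (sim$truth$loci$p0 + sim$truth$loci$p1) / 2
  expect_lt(mean(freq - expected), 0.01)     # no systematic deviation
  expect_lt(max(abs(freq - expected)), 0.35) # per-locus binomial noise only

  # large positive alpha at h = 0.5 pushes ancestry to the truncation ceiling,
  # so the admixed allele frequency approaches p1
  phi <- cline_phi(0.5, 4, 0)
  expect_equal(phi, 1 - 1e-6)
  sim4 <- simulate_hybrid_zone(
    n_loci_autosomal = 400, n_loci_x = 0, n_parental0 = 2, n_parental1 = 2,
    n_admixed = 100, hybrid_index = 0.5, true_alpha = 4,
    allele_freq_divergence = 0.9, seed = 8
  )
  adm4 <- sim4$samples$population == "admixed"
  freq4 <- rowMeans(sim4$genotypes[, adm4]) / 2
  expect_lt(mean(abs(freq4 - sim4$truth$loci$p1)), 0.03)
})

test_that("admixed genotype frequencies match binomial(2, q) by chi-square", {
  h0 <- 0.37
  a0 <- 0.4
  b0 <- -0.3
  sim <- simulate_hybrid_zone(
    n_loci_autosomal = 5, n_loci_x = 0, n_parental0 = 2, n_parental1 = 2,
    n_admixed = 5000, hybrid_index = h0, true_alpha = a0, true_beta = b0,
    allele_freq_divergence = 0.6, seed = 9
  )
  adm <- sim$samples$population == "admixed"
  tl <- sim$truth$loci
  for (j in seq_len(nrow(tl))) {
    phi <- cline_phi(h0, tl$alpha[j], tl$beta[j])
    q <- phi * tl$p1[j] + (1 - phi) * tl$p0[j]
    obs <- tabulate(sim$genotypes[j, adm] + 1L, nbins = 3L)
    expected_p <- dbinom(0:2, 2, q)
    keep <- expected_p > 0
    chi <- suppressWarnings(
      stats::chisq.test(obs[keep], p = expected_p[keep] / sum(expected_p[keep]))
    )
    expect_gt(chi$p.value, 1e-3)
  }
})

test_that("simulated hybrid-zone files round-trip through the panel reader", {
  d <- withr::local_tempdir()
  sim <- simulate_hybrid_zone(
    n_loci_autosomal = 30, n_loci_x = 5, n_parental0 = 4, n_parental1 = 4,
    n_admixed = 8, seed = 5, out_dir = d
  )
  panel <- load_variants(sim$paths[["vcf"]], sim$paths[["samples"]])
  expect_equal(unname(panel$gt), unname(sim$genotypes))
  expect_equal(unname(panel$dp), unname(sim$depth))
  expect_equal(unname(panel$ad_alt), unname(sim$alt_depth))
  expect_equal(panel$loci$contig, sim$loci$contig)

  # file-level determinism
  d2 <- withr::local_tempdir()
  simulate_hybrid_zone(
    n_loci_autosomal = 30, n_loci_x = 5, n_parental0 = 4, n_parental1 = 4,
    n_admixed = 8, seed = 5, out_dir = d2
  )
  expect_identical(readLines(file.path(d, "variants.vcf")),
                   readLines(file.path(d2, "variants.vcf")))

  # no admixed samples: the downstream cline stage refuses the input
  sim0 <- simulate_hybrid_zone(
    n_loci_autosomal = 10, n_loci_x = 0, n_parental0 = 4, n_parental1 = 4,
    n_admixed = 0, seed = 5, out_dir = withr::local_tempdir()
  )
  p0 <- load_variants(sim0$paths[["vcf"]], sim0$paths[["samples"]])
  expect_error(fit_clines(p0), "admixed")
})

test_that("qPCR plate simulator encodes one template doubling on X targets", {
  plate <- simulate_qpcr_plate(2, 2, ct_noise_sd = 0, seed = 3)
  expect_equal(delta_delta_ct(plate$ct, "X01", "NORM"), 1)
  expect_equal(delta_delta_ct(plate$ct, "A01", "NORM"), 0)
  expect_equal(fold_change(delta_delta_ct(plate$ct, "X02", "NORM")), 2)

  # with replicate noise the mean recovered fold-change stays near 2
  noisy <- simulate_qpcr_plate(100, 0, ct_noise_sd = 0.2, seed = 11)
  folds <- quantify_targets(noisy$ct, "NORM")
  expect_gt(mean(folds$fold), 1.9)
  expect_lt(mean(folds$fold), 2.1)
})

test_that("alignment simulator writes parseable PAF consistent with truth", {
  truth <- tibble::tibble(
    contig = sprintf("c%03d", 1:400),
    linkage = rep(c("X", "autosomal"), c(100, 300)),
    length = rep(20000L, 400)
  )
  path <- withr::local_tempfile(fileext = ".paf")
  rec <- simulate_alignments(truth, x_hit_rate = 0.8, map_rate = 1, seed = 2,
                             path = path)
  back <- read_paf(path)
  expect_equal(nrow(back), nrow(rec))
  asg <- assign_contigs(back)
  joined <- dplyr::left_join(truth, asg, by = c(contig = "query_id"))
  x_rate <- mean(joined$assigned_chrom[joined$linkage == "X"] == "chrX", na.rm = TRUE)
  expect_gt(x_rate, 0.7)
  expect_lt(x_rate, 0.9)
})
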