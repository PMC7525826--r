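#' Distribution specifications for simulator parameters
#'
#' Small named-distribution helpers used by [simulate_hybrid_zone()] for the
#' true cline parameters and the hybrid-index distribution. Alternatively, a
#' plain numeric vector of per-locus (or per-individual) values can be passed
#' directly wherever a `dist_*()` is accepted.
#'
#' @param value Point-mass value.
#' @param mean,sd Normal parameters (`sd >= 0`).
#' @param shape1,shape2 Beta parameters (> 0).
#' @param min,max Uniform bounds.
#' @return A list of class `xintro_dist`.
#' @export
dist_point <- function(value) structure(list(dist = "point", value = value), class = "xintro_dist")

#' @rdname dist_point
#' @export
dist_normal <- function(mean = 0, sd = 1) {
  assert_positive(sd, "sd", strict = FALSE)
  structure(list(dist = "normal", mean = mean, sd = sd), class = "xintro_dist")
}

#' @rdname dist_point
#' @export
dist_beta <- function(shape1 = 0.8, shape2 = 0.8) {
  assert_positive(shape1, "shape1"); assert_positive(shape2, "shape2")
  structure(list(dist = "beta", shape1 = shape1, shape2 = shape2), class = "xintro_dist")
}

#' @rdname dist_point
#' @export
dist_uniform <- function(min = 0, max = 1) {
  assert_that(min <= max, "`min` must not exceed `max`")
  structure(list(dist = "uniform", min = min, max = max), class = "xintro_dist")
}

draw_dist <- function(spec, n, name, lower = -Inf, upper = Inf) {
  x <- if (is.numeric(spec)) {
    assert_that(length(spec) %in% c(1L, n),
                sprintf("`%s` must have length 1 or %d", name, n))
    rep_len(spec, n)
  } else if (inherits(spec, "xintro_dist")) {
    switch(spec$dist,
      point   = rep(spec$value, n),
      normal  = rnorm(n, spec$mean, spec$sd),
      beta    = rbeta(n, spec$shape1, spec$shape2),
      uniform = runif(n, spec$min, spec$max),
      abort(sprintf("unknown distribution `%s`", spec$dist))
    )
  } else {
    abort(sprintf("`%s` must be numeric or a dist_*() specification", name))
  }
  assert_that(all(x >= lower & x <= upper),
              sprintf("`%s` produced values outside [%g, %g]", name, lower, upper))
  x
}

#' Simulate hybrid-zone SNP data under the genomic cline model
#'
#' Generates the full input set for the cline stage: genotypes for two parental
#' populations and an admixed population at unlinked biallelic SNPs, with
#' allele-specific read depths, a sample sheet, and the generating truth.
#'
#' Parental-0 and parental-1 individuals draw genotypes `Binomial(2, p)` from
#' their population allele frequency. For an admixed individual of hybrid index
#' `h`, each of the two gene copies at locus `j` derives from parental
#' population 1 with probability `phi(h, alpha_j, beta_j)` (the genomic cline
#' function, see [cline_phi()]) and then carries the alternate allele with that
#' parent's frequency; the genotype is therefore `Binomial(2, q)` with
#' `q = phi * p1 + (1 - phi) * p0`. Allele frequencies are drawn as
#' `p0 ~ Uniform(0, 1)` with `p1 = p0 +/- allele_freq_divergence` (random sign,
#' clipped to `[0, 1]`). Read depths are Poisson around `read_depth_mean` and
#' alternate-read counts binomial with per-read error `seq_error`.
#'
#' Defaults mirror a reduced-representation hybrid-zone panel: 97 X-linked and
#' 10,256 autosomal SNPs typed in 17 + 23 parental and 48 admixed females, with
#' a Beta(0.8, 0.8) hybrid-index distribution emulating a multigeneration
#' hybrid swarm containing both backcross directions.
#'
#' @param n_loci_autosomal,n_loci_x Number of autosomal / X-linked loci (each on
#'   its own contig).
#' @param n_parental0,n_parental1,n_admixed Sample sizes; all simulated
#'   individuals are female (X-linked loci in males are hemizygous and would
#'   bias cline estimates, so the analysis set is female-only).
#' @param allele_freq_divergence Expected `|p1 - p0|` per locus before clipping.
#' @param true_alpha,true_beta Per-locus cline parameters: numeric vector
#'   (length 1 or `n_loci`, X loci first) or a [dist_point()]-style spec.
#' @param hybrid_index Per-admixed-individual hybrid index in `[0, 1]`: numeric
#'   vector or distribution spec.
#' @param read_depth_mean Mean sequencing depth per genotype.
#' @param seq_error Per-read sequencing error in `[0, 0.5)`.
#' @param phi_truncation Truncation bound applied to the cline function.
#' @param seed Integer seed.
#' @param out_dir Optional directory; when given, writes `variants.vcf`,
#'   `samples.tsv`, `allele_depths.tsv` and `truth.json` and records the paths.
#'
#' @return A list with `genotypes` (loci x samples integer matrix of alt-allele
#'   copies), `depth`, `alt_depth` (matching matrices), `loci` and `samples`
#'   tibbles, `truth` (list of `loci` and `individuals` tibbles), and `paths`
#'   when `out_dir` was given.
#' @examples
#' sim <- simulate_hybrid_zone(n_loci_autosomal = 20, n_loci_x = 5,
#'                             n_admixed = 10, seed = 1)
#' sim$truth$individuals
#' @export
simulate_hybrid_zone <- function(n_loci_autosomal = 10256, n_loci_x = 97,
                                 n_parental0 = 17, n_parental1 = 23,
                                 n_admixed = 48,
                                 allele_freq_divergence = 0.5,
                                 true_alpha = dist_point(0),
                                 true_beta = dist_point(0),
                                 hybrid_index = dist_beta(0.8, 0.8),
                                 read_depth_mean = 20, seq_error = 0.005,
                                 phi_truncation = 1e-6,
                                 seed = 1, out_dir = NULL) {
  assert_count(n_loci_autosomal, "n_loci_autosomal")
  assert_count(n_loci_x, "n_loci_x", min = 0L)
  assert_count(n_parental0, "n_parental0")
  assert_count(n_parental1, "n_parental1")
  assert_count(n_admixed, "n_admixed", min = 0L)
  assert_fraction(allele_freq_divergence, "allele_freq_divergence")
  assert_positive(read_depth_mean, "read_depth_mean")
  assert_that(is.numeric(seq_error) && seq_error >= 0 && seq_error < 0.5,
              "`seq_error` must lie in [0, 0.5)")

  n_loci <- n_loci_x + n_loci_autosomal
  loci <- tibble(
    locus_id = sprintf("L%05d", seq_len(n_loci)),
    contig = c(sprintf("xcontig%05d", seq_len(n_loci_x)),
               sprintf("acontig%05d", seq_len(n_loci_autosomal))),
    pos = 0L,
    linkage = rep(c("X", "autosomal"), c(n_loci_x, n_loci_autosomal))
  )
  samples <- tibble(
    sample_id = c(sprintf("P0_%03d", seq_len(n_parental0)),
                  sprintf("P1_%03d", seq_len(n_parental1)),
                  sprintf("AD_%03d", seq_len(n_admixed))),
    population = rep(c("parental0", "parental1", "admixed"),
                     c(n_parental0, n_parental1, n_admixed)),
    sex = "F"
  )

  with_seed(seed, {
    loci$pos <- sample.int(100000L, n_loci, replace = TRUE)
    alpha <- draw_dist(true_alpha, n_loci, "true_alpha")
    beta <- draw_dist(true_beta, n_loci, "true_beta")
    h <- draw_dist(hybrid_index, n_admixed, "hybrid_index", lower = 0, upper = 1)
    p0 <- runif(n_loci)
    sgn <- sample(c(-1, 1), n_loci, replace = TRUE)
    p1 <- pmin(1, pmax(0, p0 + sgn * allele_freq_divergence))

    n_samp <- nrow(samples)
    geno <- matrix(NA_integer_, n_loci, n_samp,
                   dimnames = list(loci$locus_id, samples$sample_id))
    for (k in seq_len(n_samp)) {
      q <- switch(samples$population[k],
        parental0 = p0,
        parental1 = p1,
        admixed = {
          phi <- cline_phi(h[match(samples$sample_id[k],
                                   samples$sample_id[samples$population == "admixed"])],
                           alpha, beta, truncation = phi_truncation)
          phi * p1 + (1 - phi) * p0
        })
      geno[, k] <- rbinom(n_loci, 2L, q)
    }

    depth <- matrix(rpois(n_loci * n_samp, read_depth_mean), n_loci, n_samp,
                    dimnames = dimnames(geno))
    p_alt_read <- (geno / 2) * (1 - seq_error) + (1 - geno / 2) * seq_error
    alt <- matrix(rbinom(n_loci * n_samp, depth, p_alt_read), n_loci, n_samp,
                  dimnames = dimnames(geno))

    h_full <- ifelse(samples$population == "parental1", 1, 0)
    h_full[samples$population == "admixed"] <- h
    truth <- list(
      loci = mutate(loci, p0 = p0, p1 = p1, alpha = alpha, beta = beta),
      individuals = mutate(samples, h = h_full)
    )
    out <- list(genotypes = geno, depth = depth, alt_depth = alt,
                loci = loci, samples = samples, truth = truth)
    if (!is.null(out_dir)) out$paths <- write_hybrid_zone(out, out_dir)
    out
  })
}

# serialize a simulated hybrid zone to VCF 4.2 + TSV + truth JSON
write_hybrid_zone <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  vcf_path <- file.path(out_dir, "variants.vcf")
  samples_path <- file.path(out_dir, "samples.tsv")
  ad_path <- file.path(out_dir, "allele_depths.tsv")
  truth_path <- file.path(out_dir, "truth.json")

  gt_chr <- matrix(c("0/0", "0/1", "1/1")[sim$genotypes + 1L],
                   nrow(sim$genotypes), ncol(sim$genotypes))
  gt_chr[is.na(sim$genotypes)] <- "./."
  ref <- sim$depth - sim$alt_depth
  field <- matrix(sprintf("%s:%d:%d,%d", gt_chr, sim$depth, ref, sim$alt_depth),
                  nrow(sim$genotypes), ncol(sim$genotypes))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=xintro_simulate_hybrid_zone",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sim$samples$sample_id), collapse = "\t")
  )
  body <- paste(sim$loci$contig, sim$loci$pos, sim$loci$locus_id, "A", "T",
                ".", "PASS", ".", "GT:DP:AD",
                apply(field, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), vcf_path)

  readr::write_tsv(sim$samples, samples_path)
  ad_long <- tibble(
    locus_id = rep(rownames(sim$genotypes), ncol(sim$genotypes)),
    sample_id = rep(colnames(sim$genotypes), each = nrow(sim$genotypes)),
    ref_count = as.integer(ref),
    alt_count = as.integer(sim$alt_depth)
  )
  readr::write_tsv(ad_long, ad_path)
  jsonlite::write_json(
    list(loci = sim$truth$loci, individuals = sim$truth$individuals),
    truth_path, digits = NA
  )
  c(vcf = vcf_path, samples = samples_path, allele_depths = ad_path,
    truth = truth_path)
}
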