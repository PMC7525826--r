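write_toy_vcf <- function(path, extra_record = NULL) {
  # 2 parental0 + 2 parental1 + 1 admixed female, 1 male; 2 biallelic loci
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "p0a", "p0b", "p1a", "p1b", "ada", "mal"),
          collapse = "\t")
  )
  rec <- c(
    "tig1\t100\tv1\tA\tT\t.\tPASS\t.\tGT:DP\t0/0:20\t0/1:18\t1/1:25\t1/1:22\t0/1:19\t0/0:21",
    "tig2\t200\tv2\tG\tC\t.\tPASS\t.\tGT:DP\t0/0:30\t0/0:28\t0/1:26\t1/1:27\t./.:10\t0/1:25",
    extra_record
  )
  writeLines(c(header, rec), path)
  path
}

toy_sheet <- tibble::tibble(
  sample_id = c("p0a", "p0b", "p1a", "p1b", "ada", "mal"),
  population = c("parental0", "parental0", "parental1", "parental1",
                 "admixed", "admixed"),
  sex = c("F", "F", "F", "F", "F", "M")
)

test_that("VCF loading decodes genotypes, drops males, flags multi-allelics", {
  p <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(p, "tig3\t300\tv3\tA\tT,G\t.\tPASS\t.\tGT:DP\t0/0:9\t0/1:9\t0/0:9\t0/0:9\t0/0:9\t0/0:9")
  panel <- load_variants(p, toy_sheet)
  expect_equal(nrow(panel$loci), 3)
  expect_equal(panel$loci$biallelic, c(TRUE, TRUE, FALSE))
  expect_false("mal" %in% panel$samples$sample_id)
  expect_true(any(grepl("1 male", panel$log)))
  expect_equal(unname(panel$gt[1, ]), c(0L, 1L, 2L, 2L, 1L))
  expect_equal(unname(panel$gt[2, "ada"]), NA_integer_)
  expect_equal(unname(panel$dp[1, "p1a"]), 25)

  missing_sample <- toy_sheet[-6, ]
  expect_error(load_variants(p, missing_sample), "absent from sample sheet")
})

test_that("panel filters apply in fixed order with per-step attrition", {
  # six loci engineered to fall to one named filter each (or survive)
  gt <- rbind(
    c(0, 1, 2, 2, 1, 1, 0, 2),  # multiallelic -> biallelic filter
    c(0, 1, 2, 2, 1, 1, 0, 2),  # low depth    -> depth filter
    c(0, NA, 2, NA, 1, NA, 0, NA), # sparse parentals -> presence filter
    c(0, 0, 0, 0, 0, 0, 0, 0),  # monomorphic  -> MAF filter
    c(0, 1, 2, 2, 1, 0, 1, 2),  # survivor
    c(2, 2, 0, 0, 1, 1, 2, 0)   # survivor
  )
  pops <- rep(c("parental0", "parental1", "admixed"), c(3, 3, 2))
  dp <- matrix(20, nrow(gt), ncol(gt)); dp[2, ] <- 5
  panel <- make_panel(gt, pops, dp = dp)
  panel$loci$biallelic[1] <- FALSE

  out <- filter_variants(panel, maf_min = 0.05, mean_depth_min = 12,
                         parental_presence_min = 3)
  expect_equal(nrow(out$loci), 2)
  expect_setequal(out$loci$locus_id, c("L0005", "L0006"))
  expect_equal(sum(grepl("^filter", out$log)), 4)
  expect_match(out$log[grepl("biallelic", out$log)], "removed 1 of 6")
  expect_match(out$log[grepl("depth", out$log)], "removed 1 of 5")

  # presence rule: enough calls in EITHER parental population suffices
  gt2 <- rbind(
    c(0, 1, NA, 1, 2, NA, 1, 1), # 2 called in each parental: fails at 3
    c(0, 1, 2, NA, NA, NA, 1, 1) # 3 called in parental0, 0 in parental1: kept
  )
  panel2 <- make_panel(gt2, pops)
  out2 <- filter_variants(panel2, maf_min = 0, mean_depth_min = 0,
                          parental_presence_min = 3)
  expect_equal(out2$loci$locus_id, "L0002")

  # an emptying filter names itself
  panel3 <- make_panel(rbind(c(0, 0, 0, 0, 0, 0, 0, 0)), pops)
  expect_error(filter_variants(panel3, maf_min = 0.05, mean_depth_min = 0,
                               parental_presence_min = 1),
               "maf")
})

test_that("presence filter is monotone in the sample set", {
  set.seed(42)
  base_gt <- matrix(sample(c(0:2, NA), 120, replace = TRUE,
                           prob = c(0.3, 0.2, 0.3, 0.2)), nrow = 20)
  pops6 <- rep(c("parental0", "parental1", "admixed"), each = 2)
  pops8 <- c(pops6, "parental0", "parental1")
  extra <- matrix(sample(0:2, 40, replace = TRUE), nrow = 20)
  small <- make_panel(base_gt, pops6)
  big <- make_panel(cbind(base_gt, extra), pops8)
  keep_small <- rowSums(!is.na(small$gt[, pops6 == "parental0"])) >= 2 |
    rowSums(!is.na(small$gt[, pops6 == "parental1"])) >= 2
  keep_big <- rowSums(!is.na(big$gt[, pops8 == "parental0"])) >= 2 |
    rowSums(!is.na(big$gt[, pops8 == "parental1"])) >= 2
  expect_true(all(keep_big[keep_small]))
})

test_that("thinning keeps one SNP per contig, deterministically, and annotates", {
  gt <- matrix(rep(c(0L, 1L, 2L), 40)[1:90], nrow = 15)
  contigs <- rep(c("tigA", "tigB", "tigC"), c(5, 9, 1))
  pops <- rep(c("parental0", "parental1", "admixed"), each = 2)
  panel <- make_panel(gt, pops, contigs = contigs)

  thin1 <- thin_and_annotate(panel, validated_x = "tigA",
                             unbiased = c("tigB", "tigC"), seed = 9)
  expect_equal(nrow(thin1$loci), 3)
  expect_equal(sort(unique(thin1$loci$contig)), c("tigA", "tigB", "tigC"))
  expect_equal(thin1$loci$linkage[thin1$loci$contig == "tigA"], "X")
  thin2 <- thin_and_annotate(panel, validated_x = "tigA",
                             unbiased = c("tigB", "tigC"), seed = 9)
  expect_identical(thin1$loci, thin2$loci)

  # unresolved contigs drop out entirely
  thin3 <- thin_and_annotate(panel, validated_x = "tigA", unbiased = "tigC",
                             seed = 9)
  expect_setequal(thin3$loci$contig, c("tigA", "tigC"))

  expect_error(thin_and_annotate(panel, validated_x = "tigA", unbiased = "tigA"),
               "both sets")
})

test_that("panel writer round-trips through the loader", {
  d <- withr::local_tempdir()
  sim <- simulate_hybrid_zone(n_loci_autosomal = 25, n_loci_x = 5,
                              n_parental0 = 4, n_parental1 = 4, n_admixed = 6,
                              seed = 31, out_dir = d)
  panel <- load_variants(sim$paths[["vcf"]], sim$paths[["samples"]])
  panel <- filter_variants(panel, maf_min = 0.05, mean_depth_min = 5,
                           parental_presence_min = 3)
  out <- file.path(d, "roundtrip.vcf")
  write_panel_vcf(panel, out)
  back <- load_variants(out, sim$paths[["samples"]])
  expect_equal(back$gt, panel$gt)
  expect_equal(back$loci$contig, panel$loci$contig)
  expect_equal(back$ad_alt, panel$ad_alt)

  # parental counts are consistent sufficient statistics
  pc <- parental_counts(panel)
  expect_true(all(pc$alt0 <= pc$n0) && all(pc$alt1 <= pc$n1))
  g0 <- panel$gt[, panel$samples$population == "parental0", drop = FALSE]
  expect_equal(pc$alt0, unname(rowSums(g0, na.rm = TRUE)))
})

test_that("tidy() produces a long genotype table", {
  gt <- matrix(c(0L, 1L, 2L, NA), nrow = 2)
  panel <- make_panel(gt, c("parental0", "admixed"))
  td <- tidy(panel)
  expect_equal(nrow(td), 4)
  expect_setequal(names(td), c("locus_id", "contig", "linkage", "sample_id",
                               "population", "genotype", "depth"))
  expect_equal(td$genotype, c(0L, 1L, 2L, NA))
})
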