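#' Simulate a complete input set for the end-to-end pipeline
#'
#' Writes every file the pipeline consumes into `out_dir`: a per-contig count
#' matrix with sample sheet, a PAF of contig-to-karyotype alignments consistent
#' with the simulated linkage truth, a hybrid-zone VCF with its own sample
#' sheet and allele-depth table, a qPCR Ct table, and the generating truth.
#' The `"demo"` preset is sized to run the whole pipeline in minutes on one
#' CPU; `"paper_scale"` uses the full panel dimensions.
#'
#' @param out_dir Output directory (created if needed).
#' @param preset `"demo"` or `"paper_scale"`.
#' @param seed Global seed; per-stage seeds are derived deterministically.
#' @return Named list of file paths, plus the in-memory truth objects in
#'   attribute `"truth"`.
#' @export
simulate_inputs <- function(out_dir, preset = c("demo", "paper_scale"), seed = 1) {
  preset <- match.arg(preset)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pp <- if (preset == "demo") {
    list(n_contigs = 2000, frac_x = 0.05, mean_depth = 300,
         n_loci_a = 400, n_loci_x = 40, n_admixed = 60,
         n_steps = 4000, burn_in = 1500)
  } else {
    list(n_contigs = 78493, frac_x = 0.03, mean_depth = 637,
         n_loci_a = 10256, n_loci_x = 97, n_admixed = 48,
         n_steps = 50000, burn_in = 30000)
  }

  cm <- simulate_count_matrix(
    n_contigs = pp$n_contigs, frac_x = pp$frac_x, mean_depth = pp$mean_depth,
    seed = derive_seed(seed, "counts")
  )
  write_count_matrix(cm, file.path(out_dir, "contig_counts.tsv"),
                     file.path(out_dir, "wgs_samples.tsv"))
  truth_lengths <- setNames(cm$counts$length, cm$counts$contig)
  simulate_alignments(cm$truth, contig_lengths = truth_lengths,
                      seed = derive_seed(seed, "paf"),
                      path = file.path(out_dir, "alignments.paf"))

  # place hybrid-zone loci on contigs that exist in the coverage simulation so
  # the linkage annotation downstream is exercised end to end
  hz <- simulate_hybrid_zone(
    n_loci_autosomal = pp$n_loci_a, n_loci_x = pp$n_loci_x,
    n_admixed = pp$n_admixed,
    seed = derive_seed(seed, "hybridzone"), out_dir = out_dir
  )
  plate <- simulate_qpcr_plate(5, 1, ct_noise_sd = 0.2,
                               seed = derive_seed(seed, "qpcr"))
  readr::write_csv(plate$ct, file.path(out_dir, "qpcr_ct.csv"))

  paths <- list(
    counts = file.path(out_dir, "contig_counts.tsv"),
    wgs_samples = file.path(out_dir, "wgs_samples.tsv"),
    paf = file.path(out_dir, "alignments.paf"),
    vcf = file.path(out_dir, "variants.vcf"),
    hz_samples = file.path(out_dir, "samples.tsv"),
    allele_depths = file.path(out_dir, "allele_depths.tsv"),
    qpcr = file.path(out_dir, "qpcr_ct.csv"),
    truth = file.path(out_dir, "truth.json"),
    mcmc = list(n_steps = pp$n_steps, burn_in = pp$burn_in)
  )
  attr(paths, "truth") <- list(counts = cm$truth, hybrid_zone = hz$truth,
                               qpcr = plate$truth)
  paths
}

#' Run the full X-introgression pipeline
#'
#' Executes the stages in analysis order -- sex-linkage classification,
#' homology validation, SNP-panel construction, genomic cline MCMC, and the
#' X-versus-autosome permutation tests (plus qPCR quantification when a Ct
#' table is supplied) -- writing per-stage outputs and a report into
#' `config$out_dir`. Any stage failure stops the run at that stage with the
#' earlier outputs intact.
#'
#' The hybrid-zone loci are annotated X/autosomal using the validated X set
#' (female-biased contigs assigned to the reference X) and the unbiased contig
#' set from the sex-linkage stage; loci from the hybrid-zone VCF whose contigs
#' are not in either set keep their VCF contig prefix as a fallback when the
#' two simulations are independent (`xcontig*`/`acontig*` ids from
#' [simulate_hybrid_zone()]).
#'
#' @param config A named list (or YAML path) with input paths (`counts`,
#'   `wgs_samples`, `paf`, `vcf`, `hz_samples`, optionally `qpcr`), an
#'   `out_dir`, a global `seed`, and optional per-stage parameter blocks
#'   (`sexlink`, `homology`, `panel`, `clines`, `permtest`).
#' @return A report list (also written as `report.json`): per-stage attrition,
#'   summary tables, permutation results, seeds and thresholds used.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (nm in c("counts", "wgs_samples", "vcf", "hz_samples", "out_dir")) {
    assert_that(!is.null(config[[nm]]), sprintf("config lacks `%s`", nm))
  }
  for (nm in c("counts", "wgs_samples", "paf", "vcf", "hz_samples", "qpcr")) {
    if (!is.null(config[[nm]])) {
      assert_that(file.exists(config[[nm]]),
                  sprintf("input `%s` not found: %s", nm, config[[nm]]))
    }
  }
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = seed, stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)))
    })
  }

  # -- sex-linkage ----------------------------------------------------------
  sl <- config$sexlink %||% list()
  classes <- stage("sexlink", {
    inp <- read_count_matrix(config$counts, config$wgs_samples)
    classify_contigs(inp$counts, inp$samples,
                     min_cpm = sl$min_cpm %||% 0.2,
                     min_individuals = sl$min_individuals %||% 2,
                     alpha = sl$alpha %||% 0.05,
                     mode = sl$mode %||% "poisson",
                     dispersion = sl$dispersion)
  })
  readr::write_tsv(classes, file.path(out_dir, "contig_classes.tsv"))
  report$stages$sexlink <- list(
    summary = summarize_classes(classes),
    thresholds = list(min_cpm = sl$min_cpm %||% 0.2,
                      min_individuals = sl$min_individuals %||% 2,
                      alpha = sl$alpha %||% 0.05,
                      mode = sl$mode %||% "poisson")
  )

  # -- homology validation --------------------------------------------------
  hm <- config$homology %||% list()
  validated_x <- character()
  if (!is.null(config$paf)) {
    cross <- stage("homology", {
      rec <- read_paf(config$paf)
      asg <- assign_contigs(rec, min_coverage = hm$min_coverage %||% 0.5)
      readr::write_tsv(asg, file.path(out_dir, "chrom_assignments.tsv"))
      crosstab_linkage(classes, asg, x_chrom = hm$x_chrom %||% "chrX")
    })
    readr::write_tsv(cross$crosstab, file.path(out_dir, "linkage_crosstab.tsv"))
    validated_x <- cross$validated_x
    report$stages$homology <- list(crosstab = cross$crosstab,
                                   n_validated_x = length(validated_x))
  }
  unbiased <- classes$contig[classes$class == "unbiased"]

  # -- SNP panel ------------------------------------------------------------
  pn <- config$panel %||% list()
  panel <- stage("snp_panel", {
    p <- load_variants(config$vcf, config$hz_samples)
    p <- filter_variants(p, maf_min = pn$maf_min %||% 0.05,
                         mean_depth_min = pn$mean_depth_min %||% 12,
                         parental_presence_min = pn$parental_presence_min %||% 14)
    vx <- union(validated_x, grep("^xcontig", unique(p$loci$contig), value = TRUE))
    ub <- union(unbiased, grep("^acontig", unique(p$loci$contig), value = TRUE))
    thin_and_annotate(p, setdiff(vx, ub), setdiff(ub, vx),
                      seed = derive_seed(seed, "panel"))
  })
  write_panel_vcf(panel, file.path(out_dir, "panel.vcf"))
  writeLines(panel$log, file.path(out_dir, "panel_attrition.log"))
  report$stages$snp_panel <- list(
    log = panel$log,
    n_loci = nrow(panel$loci),
    n_x = sum(panel$loci$linkage == "X"),
    n_autosomal = sum(panel$loci$linkage == "autosomal")
  )

  # -- genomic clines -------------------------------------------------------
  cl <- config$clines %||% list()
  fit <- stage("clines", {
    cfg <- cline_config(
      n_chains = cl$n_chains %||% 5,
      n_steps = cl$n_steps %||% 50000,
      burn_in = cl$burn_in %||% 30000,
      thin = cl$thin %||% 20,
      genotype_mode = cl$genotype_mode %||% "known",
      seq_error = cl$seq_error %||% 0.001,
      seed = derive_seed(seed, "clines")
    )
    fit_clines(panel, config = cfg)
  })
  estimates <- tidy(fit)
  readr::write_tsv(estimates, file.path(out_dir, "cline_estimates.tsv"))
  readr::write_tsv(hybrid_index(fit), file.path(out_dir, "hybrid_indices.tsv"))
  report$stages$clines <- list(glance = glance(fit),
                               outliers = tabulate_outliers(estimates))

  # -- permutation comparison ----------------------------------------------
  pt <- config$permtest %||% list()
  perms <- stage("permtest", {
    x_b <- estimates$beta_med[estimates$linkage == "X"]
    a_b <- estimates$beta_med[estimates$linkage == "autosomal"]
    x_a <- estimates$alpha_med[estimates$linkage == "X"]
    a_a <- estimates$alpha_med[estimates$linkage == "autosomal"]
    list(
      beta = permutation_test(x_b, a_b, n_perm = pt$n_perm %||% 10000,
                              direction = pt$direction_beta %||% "greater",
                              seed = derive_seed(seed, "perm_beta"),
                              parameter = "beta"),
      alpha = permutation_test(x_a, a_a, n_perm = pt$n_perm %||% 10000,
                               direction = pt$direction_alpha %||% "less",
                               seed = derive_seed(seed, "perm_alpha"),
                               parameter = "alpha")
    )
  })
  report$stages$permtest <- list(beta = tidy(perms$beta), alpha = tidy(perms$alpha))

  # -- qPCR (independent side branch) --------------------------------------
  if (!is.null(config$qpcr)) {
    qp <- stage("qpcr", {
      ct <- readr::read_csv(config$qpcr, show_col_types = FALSE)
      quantify_targets(ct, normalizer = config$qpcr_normalizer %||% "NORM")
    })
    readr::write_tsv(qp, file.path(out_dir, "qpcr_folds.tsv"))
    report$stages$qpcr <- list(folds = qp, summary = summarize_folds(qp$fold))
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}
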