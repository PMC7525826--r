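#' Load a multi-sample VCF into a variant panel
#'
#' Reads genotypes, depths and allele depths from a VCF 4.2 file and attaches
#' the population and sex labels of a sample sheet. Male samples are dropped
#' (X-linked loci are hemizygous in males and would bias cline estimates in an
#' X-versus-autosome comparison), and multi-allelic records are flagged for
#' removal by the biallelic filter.
#'
#' @param vcf_path Path to a VCF file (plain or bgzipped).
#' @param sample_sheet Tibble or TSV path with columns `sample_id`,
#'   `population` (`"parental0"`, `"parental1"`, `"admixed"`), `sex`
#'   (`"F"`/`"M"`). Every VCF sample must appear in the sheet.
#' @return A `variant_panel`: a list with
#'   \describe{
#'     \item{loci}{tibble: `locus_id`, `contig`, `pos`, `ref`, `alt`,
#'       `biallelic`, `linkage` (`NA` until [thin_and_annotate()]).}
#'     \item{gt}{integer matrix (loci x samples) of alt-allele copies, `NA`
#'       for missing.}
#'     \item{dp}{numeric matrix of read depths (`NA` when absent).}
#'     \item{ad_ref,ad_alt}{numeric matrices of allele depths, or `NULL`.}
#'     \item{samples}{tibble of retained (female) samples.}
#'     \item{log}{character vector describing load/filter steps.}
#'   }
#' @export
load_variants <- function(vcf_path, sample_sheet) {
  if (is.character(sample_sheet)) {
    # sex = "F" columns must not be parsed as logical
    sample_sheet <- readr::read_tsv(sample_sheet, show_col_types = FALSE,
                                    col_types = readr::cols(.default = readr::col_character()))
  }
  assert_that(all(c("sample_id", "population", "sex") %in% names(sample_sheet)),
              "sample sheet needs columns sample_id, population, sex")
  assert_that(all(sample_sheet$population %in% c("parental0", "parental1", "admixed")),
              "population must be parental0/parental1/admixed")

  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  vcf_samples <- colnames(v@gt)[-1]
  missing <- setdiff(vcf_samples, sample_sheet$sample_id)
  assert_that(length(missing) == 0,
              sprintf("VCF samples absent from sample sheet: %s",
                      paste(head(missing, 5), collapse = ", ")))
  fmt <- unique(v@gt[, "FORMAT"])
  assert_that(all(grepl("(^|:)GT(:|$)", fmt)), "VCF FORMAT lacks a GT field")

  gt_chr <- vcfR::extract.gt(v, element = "GT")
  gt <- matrix(NA_integer_, nrow(gt_chr), ncol(gt_chr), dimnames = dimnames(gt_chr))
  clean <- gsub("\\|", "/", gt_chr)
  gt[clean %in% c("0/0")] <- 0L
  gt[clean %in% c("0/1", "1/0")] <- 1L
  gt[clean %in% c("1/1")] <- 2L

  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"), error = function(e) NULL)
  ad_ref <- ad_alt <- NULL
  if (!is.null(ad) && !all(is.na(ad))) {
    split_field <- function(x, k) {
      as.numeric(vapply(strsplit(x, ",", fixed = TRUE),
                        function(p) if (length(p) >= k) p[k] else NA_character_, ""))
    }
    ad_ref <- apply(ad, 2, split_field, k = 1L)
    ad_alt <- apply(ad, 2, split_field, k = 2L)
    dimnames(ad_ref) <- dimnames(ad_alt) <- dimnames(ad)
  }

  sheet <- sample_sheet[match(vcf_samples, sample_sheet$sample_id), ]
  keep_f <- sheet$sex == "F"
  n_males <- sum(!keep_f)
  loci <- tibble(
    locus_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                      paste0(fix$CHROM, ":", fix$POS), fix$ID),
    contig = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    biallelic = !grepl(",", fix$ALT) & fix$ALT != "." & !grepl(",", fix$REF),
    linkage = NA_character_
  )
  panel <- structure(list(
    loci = loci,
    gt = gt[, keep_f, drop = FALSE],
    dp = dp[, keep_f, drop = FALSE],
    ad_ref = if (!is.null(ad_ref)) ad_ref[, keep_f, drop = FALSE],
    ad_alt = if (!is.null(ad_alt)) ad_alt[, keep_f, drop = FALSE],
    samples = sheet[keep_f, ],
    log = c(
      sprintf("loaded %d records x %d samples from %s", nrow(loci),
              length(vcf_samples), vcf_path),
      sprintf("dropped %d male sample(s)", n_males),
      sprintf("flagged %d multi-allelic record(s)", sum(!loci$biallelic))
    )
  ), class = "variant_panel")
  rownames(panel$gt) <- loci$locus_id
  panel
}

#' @export
print.variant_panel <- function(x, ...) {
  cat(sprintf("<variant_panel> %d loci x %d samples\n", nrow(x$loci), nrow(x$samples)))
  pops <- table(x$samples$population)
  cat("  samples:", paste(sprintf("%s=%d", names(pops), pops), collapse = ", "), "\n")
  if (!all(is.na(x$loci$linkage))) {
    lk <- table(x$loci$linkage, useNA = "no")
    cat("  linkage:", paste(sprintf("%s=%d", names(lk), lk), collapse = ", "), "\n")
  }
  invisible(x)
}

panel_subset <- function(panel, keep, note) {
  panel$loci <- panel$loci[keep, , drop = FALSE]
  panel$gt <- panel$gt[keep, , drop = FALSE]
  panel$dp <- panel$dp[keep, , drop = FALSE]
  if (!is.null(panel$ad_ref)) panel$ad_ref <- panel$ad_ref[keep, , drop = FALSE]
  if (!is.null(panel$ad_alt)) panel$ad_alt <- panel$ad_alt[keep, , drop = FALSE]
  panel$log <- c(panel$log, note)
  panel
}

#' Filter a variant panel to analysis-grade SNPs
#'
#' Applies the panel filters in a fixed, logged order: biallelic records only;
#' mean read depth across samples at least `mean_depth_min`; a non-missing
#' genotype call in at least `parental_presence_min` individuals of parental
#' population 0 *or* parental population 1; minor allele frequency at least
#' `maf_min` computed over all called genotypes in all samples. The order is
#' fixed because the MAF depends on the retained locus set; each step's
#' attrition is appended to the panel log.
#'
#' @param panel A `variant_panel` from [load_variants()].
#' @param maf_min Minimum minor allele frequency.
#' @param mean_depth_min Minimum mean depth across all samples.
#' @param parental_presence_min Minimum called individuals in either parental
#'   population.
#' @param depth_over `"all"` (default) or `"called"`: samples over which the
#'   mean depth is taken.
#' @param maf_over `"all"` (default) or `"parental"`: samples over which MAF is
#'   computed.
#' @return The filtered `variant_panel`.
#' @export
filter_variants <- function(panel, maf_min = 0.05, mean_depth_min = 12,
                            parental_presence_min = 14,
                            depth_over = c("all", "called"),
                            maf_over = c("all", "parental")) {
  depth_over <- match.arg(depth_over)
  maf_over <- match.arg(maf_over)
  assert_fraction(maf_min, "maf_min")

  steps <- list(
    biallelic = function(p) p$loci$biallelic,
    depth = function(p) {
      dp <- p$dp
      if (depth_over == "called") dp[is.na(p$gt)] <- NA
      md <- rowMeans(dp, na.rm = TRUE)
      !is.na(md) & md >= mean_depth_min
    },
    presence = function(p) {
      n0 <- rowSums(!is.na(p$gt[, p$samples$population == "parental0", drop = FALSE]))
      n1 <- rowSums(!is.na(p$gt[, p$samples$population == "parental1", drop = FALSE]))
      n0 >= parental_presence_min | n1 >= parental_presence_min
    },
    maf = function(p) {
      g <- if (maf_over == "parental") {
        p$gt[, p$samples$population != "admixed", drop = FALSE]
      } else p$gt
      called <- rowSums(!is.na(g))
      alt <- rowSums(g, na.rm = TRUE)
      freq <- ifelse(called > 0, alt / (2 * called), NA_real_)
      maf <- pmin(freq, 1 - freq)
      !is.na(maf) & maf >= maf_min
    }
  )
  for (nm in names(steps)) {
    keep <- steps[[nm]](panel)
    note <- sprintf("filter %s: removed %d of %d loci", nm, sum(!keep), length(keep))
    if (!any(keep)) abort(sprintf("no locus survives the `%s` filter", nm))
    panel <- panel_subset(panel, keep, note)
  }
  panel
}

#' Thin to one SNP per contig and annotate X/autosomal linkage
#'
#' Retains exactly one locus per contig, chosen uniformly at random under
#' `seed` (SNPs on a contig tend to share their introgression signal, so one
#' per contig limits pseudo-replication). Each retained locus is annotated
#' `"X"` if its contig is in the validated X set, `"autosomal"` if in the
#' unbiased set, and is otherwise dropped as unresolved.
#'
#' @param panel A filtered `variant_panel`.
#' @param validated_x Character vector of validated X-linked contig ids.
#' @param unbiased Character vector of unbiased (autosomal) contig ids; must be
#'   disjoint from `validated_x`.
#' @param seed Integer seed for the per-contig draw.
#' @return The thinned, annotated `variant_panel`.
#' @export
thin_and_annotate <- function(panel, validated_x, unbiased, seed = 1) {
  overlap <- intersect(validated_x, unbiased)
  assert_that(length(overlap) == 0,
              sprintf("contigs in both sets: %s", paste(head(overlap, 5), collapse = ", ")))
  pick <- with_seed(derive_seed(seed, "thin"), {
    idx <- split(seq_len(nrow(panel$loci)), panel$loci$contig)
    sort(vapply(idx, function(i) if (length(i) == 1L) i else sample(i, 1L), integer(1)))
  })
  panel <- panel_subset(panel, pick,
                        sprintf("thinned to 1 SNP per contig: %d loci", length(pick)))
  linkage <- dplyr::case_when(
    panel$loci$contig %in% validated_x ~ "X",
    panel$loci$contig %in% unbiased ~ "autosomal",
    TRUE ~ "excluded"
  )
  panel$loci$linkage <- linkage
  keep <- linkage != "excluded"
  panel_subset(panel, keep,
               sprintf("dropped %d loci on unresolved contigs", sum(!keep)))
}

#' Parental allele-count sufficient statistics
#'
#' Alt-allele and called-gene-copy counts per locus in each parental
#' population; these are the sufficient statistics for the Beta posteriors on
#' parental allele frequencies used by the cline MCMC.
#'
#' @param panel A `variant_panel`.
#' @return Tibble: `locus_id`, `alt0`, `n0`, `alt1`, `n1` (gene copies, i.e.
#'   2 x called genotypes).
#' @export
parental_counts <- function(panel) {
  cnt <- function(pop) {
    g <- panel$gt[, panel$samples$population == pop, drop = FALSE]
    list(alt = unname(rowSums(g, na.rm = TRUE)),
         n = 2L * unname(rowSums(!is.na(g))))
  }
  c0 <- cnt("parental0"); c1 <- cnt("parental1")
  tibble(locus_id = panel$loci$locus_id,
         alt0 = c0$alt, n0 = c0$n, alt1 = c1$alt, n1 = c1$n)
}

#' Tidy a variant panel into a long genotype table
#'
#' @param x A `variant_panel`.
#' @param ... Unused.
#' @return Tibble: `locus_id`, `contig`, `linkage`, `sample_id`, `population`,
#'   `genotype`, `depth`.
#' @export
tidy.variant_panel <- function(x, ...) {
  tibble(
    locus_id = rep(x$loci$locus_id, ncol(x$gt)),
    contig = rep(x$loci$contig, ncol(x$gt)),
    linkage = rep(x$loci$linkage, ncol(x$gt)),
    sample_id = rep(colnames(x$gt), each = nrow(x$gt)),
    population = rep(x$samples$population, each = nrow(x$gt)),
    genotype = as.integer(x$gt),
    depth = as.numeric(x$dp)
  )
}

#' Write a variant panel back to VCF 4.2
#'
#' @param panel A `variant_panel`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  gt_chr <- matrix(c("0/0", "0/1", "1/1")[panel$gt + 1L],
                   nrow(panel$gt), ncol(panel$gt))
  gt_chr[is.na(panel$gt)] <- "./."
  dp_chr <- ifelse(is.na(panel$dp), ".", format(panel$dp, trim = TRUE, scientific = FALSE))
  if (!is.null(panel$ad_ref)) {
    ad_chr <- ifelse(is.na(panel$ad_ref), ".",
                     paste0(panel$ad_ref, ",", panel$ad_alt))
    field <- matrix(paste(gt_chr, dp_chr, ad_chr, sep = ":"), nrow(panel$gt))
    fmt <- "GT:DP:AD"
  } else {
    field <- matrix(paste(gt_chr, dp_chr, sep = ":"), nrow(panel$gt))
    fmt <- "GT:DP"
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=xintro_panel",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    if (!is.null(panel$ad_ref))
      '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples$sample_id), collapse = "\t")
  )
  body <- paste(panel$loci$contig, panel$loci$pos, panel$loci$locus_id,
                panel$loci$ref, panel$loci$alt, ".", "PASS", ".", fmt,
                apply(field, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
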