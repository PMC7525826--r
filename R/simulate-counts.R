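#' Simulate a per-contig mapped-read count matrix for sexed individuals
#'
#' Generates the idxstats-style input of the sex-linkage stage: one row per
#' assembly contig, one count column per individual, under the X-dosage model.
#' Females carry two X copies and males one, so an X-linked contig has a male
#' expectation of exactly half the female expectation, while autosomal contigs
#' have equal expectations in both sexes. Counts are negative-binomial with
#' variance `mu + dispersion * mu^2` (`dispersion = 0` gives Poisson).
#'
#' The default mean depth of 637 reads per contig corresponds to libraries of
#' 50 million read pairs spread over ~78,500 retained contigs, the scale at
#' which coverage-ratio sex-linkage screens are typically run.
#'
#' Overdispersion is modelled as a contig-level multiplicative effect shared
#' by all individuals (a Gamma-distributed mappability/repeat-content factor):
#' marginally each count is negative-binomial with the stated dispersion, while
#' the male:female contrast at a contig remains conditionally Poisson -- which
#' is what makes a coverage-ratio screen work at all, since between-individual
#' coverage noise at a fixed contig is close to Poisson after library-size
#' standardisation.
#'
#' @param n_contigs Number of contigs to simulate.
#' @param frac_x Fraction of contigs that are X-linked, in `[0, 1]`.
#' @param n_males,n_females Number of individuals of each sex (>= 1).
#' @param mean_depth Expected mapped reads per contig in a female (i.e. per
#'   two-copy locus); males expect half of this on X contigs.
#' @param nb_dispersion Negative-binomial dispersion `d` in
#'   `Var = mu + d * mu^2`; `0` degrades to Poisson.
#' @param contig_length_range Length-two vector of min/max contig length (bp);
#'   lengths are drawn uniformly and carried as metadata.
#' @param seed Integer seed; identical parameters and seed give identical output.
#'
#' @return A list with elements
#'   \describe{
#'     \item{counts}{tibble: `contig`, `length`, then one integer column per
#'       sample.}
#'     \item{samples}{tibble: `sample_id`, `sex` (`"F"`/`"M"`).}
#'     \item{truth}{tibble: `contig`, `linkage` (`"X"`/`"autosomal"`).}
#'   }
#' @examples
#' sim <- simulate_count_matrix(n_contigs = 50, frac_x = 0.2, seed = 1)
#' head(sim$counts)
#' @export
simulate_count_matrix <- function(n_contigs = 10000, frac_x = 0.03,
                                  n_males = 2, n_females = 2,
                                  mean_depth = 637, nb_dispersion = 0.05,
                                  contig_length_range = c(1000, 100000),
                                  seed = 1) {
  assert_count(n_contigs, "n_contigs")
  assert_fraction(frac_x, "frac_x")
  assert_count(n_males, "n_males")
  assert_count(n_females, "n_females")
  assert_positive(mean_depth, "mean_depth")
  assert_positive(nb_dispersion, "nb_dispersion", strict = FALSE)
  assert_that(
    length(contig_length_range) == 2L && all(contig_length_range >= 1) &&
      contig_length_range[1] <= contig_length_range[2],
    "`contig_length_range` must be an increasing pair of positive lengths"
  )

  n_x <- round(n_contigs * frac_x)
  linkage <- rep(c("X", "autosomal"), c(n_x, n_contigs - n_x))
  contig <- sprintf("contig%06d", seq_len(n_contigs))
  # equal-input design: every library is subsampled to the same read total, so
  # the stated library size is common to all individuals rather than the
  # column sum (which is depressed in males by the half-covered X contigs)
  samples <- tibble(
    sample_id = c(sprintf("F%02d", seq_len(n_females)),
                  sprintf("M%02d", seq_len(n_males))),
    sex = rep(c("F", "M"), c(n_females, n_males)),
    library_size = round(n_contigs * mean_depth)
  )

  with_seed(seed, {
    lengths <- round(runif(n_contigs, contig_length_range[1], contig_length_range[2]))
    # shared contig effect: counts are marginally NB(mu, d), Poisson given s
    s <- if (nb_dispersion == 0) rep(1, n_contigs)
         else stats::rgamma(n_contigs, shape = 1 / nb_dispersion, scale = nb_dispersion)
    mu_f <- rep(mean_depth, n_contigs)
    mu_m <- ifelse(linkage == "X", mean_depth / 2, mean_depth)
    mat <- vapply(seq_len(nrow(samples)), function(i) {
      as.numeric(rpois(n_contigs, s * (if (samples$sex[i] == "F") mu_f else mu_m)))
    }, numeric(n_contigs))
    colnames(mat) <- samples$sample_id
    list(
      counts = bind_cols_counts(contig, lengths, mat),
      samples = samples,
      truth = tibble(contig = contig, linkage = linkage)
    )
  })
}

bind_cols_counts <- function(contig, lengths, mat) {
  out <- tibble(contig = contig, length = as.integer(lengths))
  for (nm in colnames(mat)) out[[nm]] <- as.integer(mat[, nm])
  out
}

#' Write / read a count matrix in idxstats-like TSV form
#'
#' @param sim Output of [simulate_count_matrix()], or any list with `counts`
#'   and `samples` tibbles shaped the same way.
#' @param counts_path,samples_path Destination TSV paths.
#' @return `write_count_matrix()` returns the paths invisibly;
#'   `read_count_matrix()` returns a list with `counts` and `samples`.
#' @export
write_count_matrix <- function(sim, counts_path, samples_path) {
  readr::write_tsv(sim$counts, counts_path)
  readr::write_tsv(sim$samples, samples_path)
  invisible(c(counts = counts_path, samples = samples_path))
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(counts_path, samples_path) {
  counts <- readr::read_tsv(counts_path, show_col_types = FALSE)
  samples <- readr::read_tsv(
    samples_path, show_col_types = FALSE,
    col_types = readr::cols(sample_id = readr::col_character(),
                            sex = readr::col_character())
  )
  validate_count_matrix(counts, samples)
  list(counts = counts, samples = samples)
}

validate_count_matrix <- function(counts, samples) {
  assert_that(nrow(counts) > 0, "count matrix is empty")
  assert_that(
    all(c("contig", "length") == names(counts)[1:2]),
    "count table must start with columns `contig`, `length`"
  )
  assert_that(
    all(samples$sample_id %in% names(counts)),
    "every sample in the sample sheet needs a count column"
  )
  assert_that(all(samples$sex %in% c("F", "M")), "sex must be 'F' or 'M'")
  cm <- as.matrix(counts[samples$sample_id])
  assert_that(all(cm >= 0) && !anyNA(cm), "counts must be non-negative and complete")
  invisible(TRUE)
}
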