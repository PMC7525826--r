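#' Filter contigs on counts-per-million
#'
#' Contigs with low counts in all individuals carry little power to detect a
#' sex difference and are removed before testing: a contig is retained when at
#' least `min_individuals` individuals have CPM (count / library size x 1e6)
#' strictly above `min_cpm`. Library sizes are taken from `library_sizes`,
#' else from a `library_size` column of the sample sheet (the natural encoding
#' when libraries were subsampled to a common input), else computed as column
#' totals of the count matrix.
#'
#' @param counts Count tibble: `contig`, `length`, then one column per sample.
#' @param samples Sample sheet tibble with `sample_id` and `sex`.
#' @param min_cpm CPM threshold (exclusive).
#' @param min_individuals Minimum number of individuals above threshold.
#' @param library_sizes Optional named vector of total mapped reads per sample.
#' @return The retained rows of `counts`, with the dropped contig ids in
#'   attribute `"filtered_contigs"`.
#' @examples
#' sim <- simulate_count_matrix(n_contigs = 100, seed = 1)
#' kept <- cpm_filter(sim$counts, sim$samples)
#' attr(kept, "filtered_contigs")
#' @export
cpm_filter <- function(counts, samples, min_cpm = 0.2, min_individuals = 2,
                       library_sizes = NULL) {
  validate_count_matrix(counts, samples)
  assert_positive(min_cpm, "min_cpm", strict = FALSE)
  assert_count(min_individuals, "min_individuals")
  lib <- library_sizes_of(counts, samples, library_sizes)
  cm <- as.matrix(counts[samples$sample_id])
  cpm <- sweep(cm, 2L, lib, "/") * 1e6
  keep <- rowSums(cpm > min_cpm) >= min_individuals
  if (!any(keep)) {
    warn("no contig passed the CPM filter")
  }
  out <- counts[keep, , drop = FALSE]
  attr(out, "filtered_contigs") <- counts$contig[!keep]
  attr(out, "library_sizes") <- lib
  out
}

library_sizes_of <- function(counts, samples, library_sizes = NULL) {
  lib <- library_sizes %||%
    (if ("library_size" %in% names(samples)) setNames(samples$library_size, samples$sample_id)
     else colSums(as.matrix(counts[samples$sample_id])))
  lib <- lib[samples$sample_id]
  assert_that(all(lib > 0) && !anyNA(lib), "library sizes must be positive")
  lib
}

#' Exact conditional test for a sex difference in mapped-read counts
#'
#' Tests whether a contig's counts differ between males and females beyond
#' library-size expectation. Conditional on the total count `T`, the male sum
#' `S` is, under the null of a common per-read rate, `Binomial(T, pi)` with
#' `pi = sum(lib_m) / (sum(lib_m) + sum(lib_f))` when counts are Poisson. The
#' two-sided p-value sums the probabilities of all outcomes no more probable
#' than the observed one (with a `1 + 1e-12` tolerance against ties lost to
#' floating point). In `"nb"` mode the same conditional construction is applied
#' with the group sums distributed as exact convolutions of per-individual
#' negative-binomial laws (`Var = mu + d * mu^2`) at the common rate estimated
#' from the conditioning total; `dispersion = 0` reproduces the Poisson mode.
#'
#' @param counts_f,counts_m Integer counts for female / male individuals.
#' @param lib_f,lib_m Library sizes (total mapped reads) for each individual.
#' @param mode `"poisson"` or `"nb"`.
#' @param dispersion Negative-binomial dispersion `d` (required >= 0 for
#'   `"nb"`).
#' @return A single two-sided p-value in `(0, 1]`.
#' @examples
#' exact_count_test(counts_f = 8, counts_m = 2, lib_f = 1e6, lib_m = 1e6)
#' @export
exact_count_test <- function(counts_f, counts_m, lib_f, lib_m,
                             mode = c("poisson", "nb"), dispersion = NULL) {
  mode <- match.arg(mode)
  assert_that(all(c(counts_f, counts_m) >= 0) && !anyNA(c(counts_f, counts_m)),
              "counts must be non-negative")
  assert_that(all(c(lib_f, lib_m) > 0), "library sizes must be positive")
  assert_that(length(counts_f) == length(lib_f) && length(counts_m) == length(lib_m),
              "counts and library sizes must align")
  s_m <- sum(counts_m)
  total <- s_m + sum(counts_f)
  assert_that(total > 0, "at least one count must be positive")
  if (mode == "nb") {
    assert_that(!is.null(dispersion) && dispersion >= 0,
                "`dispersion` must be supplied and >= 0 in nb mode")
    if (dispersion > 0) {
      return(nb_conditional_p(s_m, total, lib_f, lib_m, dispersion))
    }
  }
  pi_m <- sum(lib_m) / (sum(lib_m) + sum(lib_f))
  conditional_p(dbinom(0:total, total, pi_m), s_m)
}

# two-sided "sum of outcomes no more probable than observed" rule
conditional_p <- function(pmf, observed) {
  pmf <- pmf / sum(pmf)
  min(1, sum(pmf[pmf <= pmf[observed + 1L] * (1 + 1e-12)]))
}

# conditional pmf of the male sum given the total, group sums being
# convolutions of per-individual NB(mu_i = lambda * lib_i, size = 1/d)
nb_conditional_p <- function(s_m, total, lib_f, lib_m, dispersion) {
  lambda <- total / (sum(lib_f) + sum(lib_m))
  pmf_m <- group_sum_pmf(lambda * lib_m, dispersion, total)
  pmf_f <- group_sum_pmf(lambda * lib_f, dispersion, total)
  joint <- pmf_m * rev(pmf_f) # P(S_m = s) * P(S_f = total - s)
  conditional_p(joint, s_m)
}

# pmf of a sum of independent NB counts on 0..total, by convolution
group_sum_pmf <- function(mus, dispersion, total) {
  size <- 1 / dispersion
  pmfs <- lapply(mus, function(mu) dnbinom(0:total, mu = mu, size = size))
  Reduce(function(a, b) truncated_convolve(a, b, total + 1L), pmfs)
}

# linear convolution truncated to the first `len` entries; direct for short
# vectors (exact arithmetic), FFT for long ones
truncated_convolve <- function(a, b, len) {
  if (len <= 1024L) {
    out <- numeric(len)
    for (i in seq_len(len)) {
      j <- seq_len(i)
      out[i] <- sum(a[j] * b[i - j + 1L])
    }
    out
  } else {
    n <- stats::nextn(2L * len, 2)
    ap <- c(a, numeric(n - len)); bp <- c(b, numeric(n - len))
    full <- Re(fft(fft(ap) * fft(bp), inverse = TRUE)) / n
    pmax(full[seq_len(len)], 0)
  }
}

# pooled method-of-moments common dispersion across contigs:
# within each sex group, E[s^2 - mean] = d * mean^2 under NB
estimate_common_dispersion <- function(cm, sex) {
  num <- 0; den <- 0
  for (s in c("F", "M")) {
    sub <- cm[, sex == s, drop = FALSE]
    if (ncol(sub) < 2L) next
    mu <- rowMeans(sub)
    v <- apply(sub, 1L, var)
    num <- num + sum(v - mu)
    den <- den + sum(mu^2)
  }
  if (den == 0) return(0)
  max(0, num / den)
}

#' Classify contigs as female-biased, male-biased, or unbiased
#'
#' Runs the full coverage-ratio sex-linkage screen: CPM filtering, an exact
#' conditional count test per contig, Benjamini-Hochberg correction, and the
#' three-way call. X-linked contigs (two copies in females, one in males) are
#' expected at a male:female log2 fold-change of -1 and appear female-biased;
#' autosomal contigs are expected at 0.
#'
#' `log2fc_mf = log2((mean CPM_M + c) / (mean CPM_F + c))`, where the
#' pseudo-count `c` is `pseudo_reads` rescaled to CPM by the mean library size,
#' stabilising the ratio for near-zero means.
#'
#' @inheritParams cpm_filter
#' @param alpha Significance level applied to the (corrected) p-values.
#' @param correction `"bh"` (Benjamini-Hochberg) or `"none"`.
#' @param mode,dispersion Passed to [exact_count_test()]; in `"nb"` mode with
#'   `dispersion = NULL` a common dispersion is moment-estimated across
#'   retained contigs.
#' @param pseudo_reads Pseudo-count in read units for the fold-change.
#' @return A `contig_class` tibble with one row per input contig: `contig`,
#'   `mean_cpm_f`, `mean_cpm_m`, `log2fc_mf`, `p_raw`, `p_adj`, `class`
#'   (`"female-biased"`, `"male-biased"`, `"unbiased"`, or `"filtered"`).
#' @examples
#' sim <- simulate_count_matrix(n_contigs = 200, frac_x = 0.1, seed = 7)
#' cls <- classify_contigs(sim$counts, sim$samples)
#' dplyr::count(cls, class)
#' @export
classify_contigs <- function(counts, samples, min_cpm = 0.2, min_individuals = 2,
                             alpha = 0.05, correction = c("bh", "none"),
                             mode = c("poisson", "nb"), dispersion = NULL,
                             pseudo_reads = 0.5, library_sizes = NULL) {
  correction <- match.arg(correction)
  mode <- match.arg(mode)
  assert_fraction(alpha, "alpha")
  assert_that(sum(samples$sex == "F") >= 1 && sum(samples$sex == "M") >= 1,
              "need at least one individual of each sex")

  kept <- cpm_filter(counts, samples, min_cpm, min_individuals, library_sizes)
  lib <- attr(kept, "library_sizes")
  filtered_ids <- attr(kept, "filtered_contigs")

  f_ids <- samples$sample_id[samples$sex == "F"]
  m_ids <- samples$sample_id[samples$sex == "M"]
  cm <- as.matrix(kept[samples$sample_id])
  if (mode == "nb" && is.null(dispersion)) {
    dispersion <- estimate_common_dispersion(cm, samples$sex[match(colnames(cm), samples$sample_id)])
  }

  cpm <- sweep(cm, 2L, lib, "/") * 1e6
  mean_cpm_f <- rowMeans(cpm[, f_ids, drop = FALSE])
  mean_cpm_m <- rowMeans(cpm[, m_ids, drop = FALSE])
  pc <- pseudo_reads / mean(lib) * 1e6
  log2fc <- log2((mean_cpm_m + pc) / (mean_cpm_f + pc))

  p_raw <- vapply(seq_len(nrow(kept)), function(i) {
    exact_count_test(cm[i, f_ids], cm[i, m_ids], lib[f_ids], lib[m_ids],
                     mode = mode, dispersion = dispersion)
  }, numeric(1))
  p_adj <- if (correction == "bh") p.adjust(p_raw, "BH") else p_raw

  cls <- dplyr::case_when(
    p_adj < alpha & log2fc < 0 ~ "female-biased",
    p_adj < alpha & log2fc > 0 ~ "male-biased",
    TRUE ~ "unbiased"
  )
  tested <- tibble(
    contig = kept$contig, mean_cpm_f = mean_cpm_f, mean_cpm_m = mean_cpm_m,
    log2fc_mf = log2fc, p_raw = p_raw, p_adj = p_adj, class = cls
  )
  out <- bind_rows(tested, tibble(
    contig = filtered_ids, mean_cpm_f = NA_real_, mean_cpm_m = NA_real_,
    log2fc_mf = NA_real_, p_raw = NA_real_, p_adj = NA_real_, class = "filtered"
  ))
  out <- out[match(counts$contig, out$contig), ]
  class(out) <- c("contig_class", class(out))
  attr(out, "dispersion") <- if (mode == "nb") dispersion else NA_real_
  attr(out, "mode") <- mode
  out
}

#' Summarise a contig classification in the style of a screen report
#'
#' One row per class with contig counts, percentages, and the mean +/- SD of
#' the male:female log2 fold-change.
#'
#' @param classes A `contig_class` tibble from [classify_contigs()].
#' @return A tibble with `class`, `n`, `pct`, `mean_log2fc`, `sd_log2fc`.
#' @export
summarize_classes <- function(classes) {
  classes |>
    group_by(class) |>
    summarise(
      n = n(),
      mean_log2fc = mean(.data$log2fc_mf),
      sd_log2fc = sd(.data$log2fc_mf),
      .groups = "drop"
    ) |>
    mutate(pct = 100 * .data$n / sum(.data$n)) |>
    select("class", "n", "pct", "mean_log2fc", "sd_log2fc")
}
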