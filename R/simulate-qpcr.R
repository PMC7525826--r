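#' Simulate a qPCR plate for X-linkage validation
#'
#' Builds a Ct table of the form used to validate candidate X-linked contigs by
#' relative quantification against an autosomal normalizer. Females carry two X
#' copies, so an X-linked target amplifies one template doubling earlier in
#' females: its true ddCt (male mean minus female mean of the
#' normalizer-corrected Ct) is +1 and its fold-change `2^ddCt = 2`. Autosomal
#' targets have ddCt 0. Per-sample template-amount offsets affect target and
#' normalizer alike and cancel in the ddCt.
#'
#' @param n_x_targets,n_autosomal_targets Numbers of candidate targets of each
#'   kind (the designated normalizer target `"NORM"` is added on top).
#' @param ct_noise_sd Standard deviation of replicate Ct noise (cycles, >= 0).
#' @param n_females,n_males Individuals of each sex (>= 1).
#' @param n_replicates Technical replicates per (target, sample).
#' @param seed Integer seed.
#' @return A list with `ct` (tibble: `target`, `sample`, `sex`, `replicate`,
#'   `ct`) and `truth` (tibble: `target`, `linkage`, `true_ddct`).
#' @examples
#' plate <- simulate_qpcr_plate(2, 1, ct_noise_sd = 0, seed = 1)
#' delta_delta_ct(plate$ct, target = "X01", normalizer = "NORM")
#' @export
simulate_qpcr_plate <- function(n_x_targets, n_autosomal_targets,
                                ct_noise_sd = 0.2, n_females = 2, n_males = 2,
                                n_replicates = 3, seed = 1) {
  assert_count(n_x_targets, "n_x_targets", min = 0L)
  assert_count(n_autosomal_targets, "n_autosomal_targets", min = 0L)
  assert_positive(ct_noise_sd, "ct_noise_sd", strict = FALSE)
  assert_count(n_females, "n_females")
  assert_count(n_males, "n_males")
  assert_count(n_replicates, "n_replicates")

  targets <- tibble(
    target = c(sprintf("X%02d", seq_len(n_x_targets)),
               sprintf("A%02d", seq_len(n_autosomal_targets)), "NORM"),
    linkage = c(rep("X", n_x_targets), rep("autosomal", n_autosomal_targets + 1L))
  )
  samples <- tibble(
    sample = c(sprintf("F%02d", seq_len(n_females)),
               sprintf("M%02d", seq_len(n_males))),
    sex = rep(c("F", "M"), c(n_females, n_males))
  )

  with_seed(seed, {
    base_ct <- runif(nrow(targets), 24, 30)          # per-assay baseline
    template <- runif(nrow(samples), -0.5, 0.5)      # per-sample DNA amount
    grid <- tidyr::expand_grid(
      target = targets$target, sample = samples$sample,
      replicate = seq_len(n_replicates)
    )
    grid <- grid |>
      left_join(targets, by = "target") |>
      left_join(samples, by = "sample") |>
      mutate(
        ct = base_ct[match(.data$target, targets$target)] +
          template[match(.data$sample, samples$sample)] -
          as.numeric(.data$linkage == "X" & .data$sex == "F") +
          rnorm(dplyr::n(), 0, ct_noise_sd)
      ) |>
      select("target", "sample", "sex", "replicate", "ct")
    list(
      ct = grid,
      truth = mutate(targets, true_ddct = as.numeric(.data$linkage == "X"))
    )
  })
}

#' Simulate pairwise-alignment (PAF) records consistent with linkage truth
#'
#' Emits homology records of simulated assembly contigs against an annotated
#' reference karyotype, for exercising the chromosome-assignment stage. True-X
#' contigs that align at all hit the reference X with probability `x_hit_rate`
#' (and an autosome otherwise); true-autosomal contigs hit the X only at rate
#' `background_x_rate`. Alignment-block coverage of mapped contigs is drawn
#' uniformly on `coverage_range`, and `matches` is coverage times length times
#' an identity factor.
#'
#' @param truth Tibble with `contig` and `linkage` columns (as produced by
#'   [simulate_count_matrix()]), plus optionally `length`.
#' @param contig_lengths Optional named lengths (bp); defaults to 10 kb.
#' @param map_rate Fraction of contigs with any alignment.
#' @param x_hit_rate P(best hit on chrX | true X contig, mapped).
#' @param background_x_rate P(best hit on chrX | autosomal contig, mapped).
#' @param coverage_range Block coverage range for mapped contigs.
#' @param autosomes Reference autosome names to draw from.
#' @param chrom_length Reference chromosome length used for target coordinates.
#' @param seed Integer seed.
#' @param path Optional file path; when given the records are also written as
#'   12-column PAF.
#' @return Tibble of alignment records (see [read_paf()] for columns).
#' @export
simulate_alignments <- function(truth, contig_lengths = NULL, map_rate = 0.6,
                                x_hit_rate = 0.75, background_x_rate = 0.034,
                                coverage_range = c(0.55, 0.95),
                                autosomes = sprintf("chr%d", 1:22),
                                chrom_length = 15e7, seed = 1, path = NULL) {
  assert_fraction(map_rate, "map_rate")
  assert_fraction(x_hit_rate, "x_hit_rate")
  assert_fraction(background_x_rate, "background_x_rate")
  lens <- contig_lengths %||%
    (if ("length" %in% names(truth)) setNames(truth$length, truth$contig)
     else setNames(rep(10000L, nrow(truth)), truth$contig))

  with_seed(seed, {
    mapped <- runif(nrow(truth)) < map_rate
    t <- truth[mapped, , drop = FALSE]
    n <- nrow(t)
    hit_x <- runif(n) < ifelse(t$linkage == "X", x_hit_rate, background_x_rate)
    chrom <- ifelse(hit_x, "chrX", sample(autosomes, n, replace = TRUE))
    qlen <- as.integer(lens[t$contig])
    cov <- runif(n, coverage_range[1], coverage_range[2])
    alen <- pmax(1L, as.integer(round(cov * qlen)))
    qstart <- as.integer(floor(runif(n, 0, qlen - alen + 1)))
    tstart <- as.integer(floor(runif(n, 0, chrom_length - alen)))
    rec <- tibble(
      query_id = t$contig, query_length = qlen,
      query_start = qstart, query_end = qstart + alen,
      strand = sample(c("+", "-"), n, replace = TRUE),
      target_chrom = chrom, target_length = as.integer(chrom_length),
      target_start = tstart, target_end = tstart + alen,
      matches = as.integer(round(alen * runif(n, 0.85, 0.99))),
      block_len = alen, mapq = 60L
    )
    if (!is.null(path)) write_paf(rec, path)
    rec
  })
}

#' @rdname simulate_alignments
#' @param records Tibble of alignment records.
#' @export
write_paf <- function(records, path) {
  lines <- with(records, paste(query_id, query_length, query_start, query_end,
                               strand, target_chrom, target_length, target_start,
                               target_end, matches, block_len, mapq, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
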