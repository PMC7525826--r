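#' Plot the male:female log2 fold-change distribution by contig class
#'
#' X-linked contigs are expected near the dashed line at -1 (one X copy in
#' males versus two in females); autosomal contigs near 0.
#'
#' @param object A `contig_class` tibble from [classify_contigs()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.contig_class <- function(object, ...) {
  df <- dplyr::filter(object, .data$class != "filtered")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc_mf, fill = .data$class)) +
    ggplot2::geom_histogram(bins = 80, position = "identity", alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-1, 0), linetype = "dashed") +
    ggplot2::labs(x = expression(log[2] ~ FC ~ (M:F)), y = "contigs",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot fitted genomic clines
#'
#' Draws the posterior-median cline `phi(h)` for each locus, coloured by
#' linkage; the diagonal is the neutral cline `phi = h`.
#'
#' @param object A `cline_fit`.
#' @param max_loci Cap on the number of loci drawn (thinned evenly).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cline_fit <- function(object, max_loci = 200, ...) {
  est <- tidy(object)
  if (nrow(est) > max_loci) {
    est <- est[seq(1L, nrow(est), length.out = max_loci), ]
  }
  grid <- tidyr::expand_grid(locus_id = est$locus_id, h = seq(0, 1, 0.02)) |>
    left_join(select(est, "locus_id", "linkage", "alpha_med", "beta_med"),
              by = "locus_id") |>
    mutate(phi = cline_phi(.data$h, .data$alpha_med, .data$beta_med))
  ggplot2::ggplot(grid, ggplot2::aes(.data$h, .data$phi, group = .data$locus_id,
                                     colour = .data$linkage)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "hybrid index h", y = expression(phi),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a permutation null distribution
#'
#' Histogram of the permuted autosomal-set means with the observed X-set mean
#' as a dashed vertical line; an observed mean in the far tail of the stated
#' direction indicates a distinct pattern of introgression for the X.
#'
#' @param object A `perm_test`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.perm_test <- function(object, bins = 50, ...) {
  df <- tibble(null_mean = object$null_means)
  ggplot2::ggplot(df, ggplot2::aes(.data$null_mean)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey60") +
    ggplot2::geom_vline(xintercept = object$observed_mean_x, linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("permuted autosomal mean%s",
                  if (is.na(object$parameter)) "" else paste0(" (", object$parameter, ")")),
      y = "permutations",
      subtitle = sprintf("observed mean(X) = %.3f, empirical p = %.4g",
                         object$observed_mean_x, object$empirical_p)
    ) +
    ggplot2::theme_minimal()
}

#' Plot qPCR fold-changes against the X-linkage expectation
#'
#' @param folds Tibble from [quantify_targets()].
#' @return A ggplot with reference lines at fold 1 (autosomal) and 2
#'   (X-linked).
#' @export
plot_qpcr_folds <- function(folds) {
  ggplot2::ggplot(folds, ggplot2::aes(.data$target, .data$fold)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_hline(yintercept = c(1, 2), linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "fold-change (2^ddCt)") +
    ggplot2::theme_minimal()
}
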