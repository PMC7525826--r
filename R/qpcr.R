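#' Relative quantification (ddCt) of a candidate X-linked target
#'
#' For each sample, replicate Ct values are averaged and the target is
#' normalised against the autosomal normalizer: `dCt = mean Ct(target) -
#' mean Ct(normalizer)`. The between-sex contrast is `ddCt = mean over males of
#' dCt - mean over females of dCt`, signed so that one extra template doubling
#' in females (the X-linkage expectation: two X copies versus one) gives
#' `ddCt = +1`. Adding a constant to every Ct (a plate shift) leaves the result
#' unchanged.
#'
#' @param ct Ct tibble with columns `target`, `sample`, `sex` (`"F"`/`"M"`),
#'   `replicate`, `ct` (cycles, > 0).
#' @param target Target id to quantify.
#' @param normalizer Normalizer target id; must be measured in every sample of
#'   the target.
#' @return The ddCt value (a single number).
#' @examples
#' plate <- simulate_qpcr_plate(1, 0, ct_noise_sd = 0, seed = 1)
#' delta_delta_ct(plate$ct, "X01", "NORM") # 1: one template doubling
#' @export
delta_delta_ct <- function(ct, target, normalizer) {
  assert_that(all(c("target", "sample", "sex", "ct") %in% names(ct)),
              "`ct` needs columns target, sample, sex, replicate, ct")
  assert_that(all(ct$ct > 0), "Ct values must be positive")
  assert_that(target %in% ct$target, sprintf("target `%s` not measured", target))
  assert_that(normalizer %in% ct$target,
              sprintf("normalizer `%s` not measured", normalizer))
  tname <- target
  nname <- normalizer
  per_sample <- ct |>
    filter(.data$target %in% c(tname, nname)) |>
    group_by(.data$sample, .data$sex, .data$target) |>
    summarise(mean_ct = mean(.data$ct), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "target", values_from = "mean_ct")
  assert_that(!anyNA(per_sample[[nname]]),
              "normalizer missing for some sample")
  per_sample <- per_sample[!is.na(per_sample[[tname]]), ]
  per_sample$dct <- per_sample[[tname]] - per_sample[[nname]]
  assert_that(any(per_sample$sex == "F") && any(per_sample$sex == "M"),
              "target must be measured in both sexes")
  mean(per_sample$dct[per_sample$sex == "M"]) -
    mean(per_sample$dct[per_sample$sex == "F"])
}

#' Fold-change implied by a ddCt value
#'
#' Template fold-change between the sexes under an assumed amplification
#' efficiency of exactly 2: `fold = 2^ddCt`. An X-linked target is expected at
#' `ddCt = 1`, i.e. a fold-change of 2 (two X copies in females versus one in
#' males); an autosomal target at `ddCt = 0`, fold-change 1.
#'
#' @param ddct ddCt value(s).
#' @return `2^ddct`, unrounded (reports round to 2 decimals).
#' @examples
#' fold_change(c(0.92, 1.14, 1.17))
#' @export
fold_change <- function(ddct) {
  assert_that(all(is.finite(ddct)), "`ddct` must be finite")
  2^ddct
}

#' Mean and standard deviation of fold-changes
#'
#' @param folds At least two fold-change values.
#' @return One-row tibble with `n`, `mean`, `sd` (sample, n-1 denominator).
#' @examples
#' summarize_folds(c(1.89, 2.94, 2.20, 2.25, 1.65))
#' @export
summarize_folds <- function(folds) {
  assert_that(length(folds) >= 2, "need at least 2 fold-change values")
  tibble(n = length(folds), mean = mean(folds), sd = sd(folds))
}

#' Quantify every non-normalizer target on a plate
#'
#' @inheritParams delta_delta_ct
#' @return Tibble: `target`, `ddct`, `fold`.
#' @export
quantify_targets <- function(ct, normalizer) {
  targets <- setdiff(unique(ct$target), normalizer)
  tibble(
    target = targets,
    ddct = vapply(targets, delta_delta_ct, numeric(1), ct = ct,
                  normalizer = normalizer, USE.NAMES = FALSE)
  ) |>
    mutate(fold = fold_change(.data$ddct))
}
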