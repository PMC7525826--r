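#' Permutation test of X-linked versus autosomal cline parameters
#'
#' Tests whether the mean cline-parameter point estimate of the X-linked SNP
#' set is more extreme than expected from the autosomal background. Each of
#' `n_perm` permutations samples `length(x_values)` autosomal estimates without
#' replacement and records their mean; the X set is called distinct
#' (`significant`) when its observed mean is more extreme than the permuted
#' mean in more than 95% of permutations, in the stated direction. The
#' direction is an explicit a-priori argument (`"greater"` is the usual choice
#' for `beta`, reduced introgression; `"less"` for `alpha`, excess
#' parental-0 ancestry) and is never inferred from the data.
#'
#' `empirical_p` is the add-one-corrected tail probability
#' `(1 + #{null means at least as extreme}) / (n_perm + 1)`, which cannot be
#' zero; the raw >95% decision rule is kept separately in `significant`.
#'
#' @param x_values Point estimates of the X-linked set (length >= 2).
#' @param a_values Point estimates of the autosomal pool (longer than
#'   `x_values`).
#' @param n_perm Number of permutations.
#' @param direction `"greater"` or `"less"`; must be supplied explicitly.
#' @param seed Integer seed.
#' @param parameter Optional label (`"alpha"`/`"beta"`) carried into the
#'   result.
#' @return A `perm_test` list: `parameter`, `direction`, `observed_mean_x`,
#'   `n_x`, `n_perm`, `null_means`, `empirical_p`, `significant`. [tidy()]
#'   gives a one-row tibble (without the null draws), [autoplot()] the
#'   null-distribution histogram.
#' @examples
#' pt <- permutation_test(rnorm(10, 1), rnorm(200), n_perm = 999,
#'                        direction = "greater", seed = 1)
#' tidy(pt)
#' @export
permutation_test <- function(x_values, a_values, n_perm = 10000,
                             direction = c("greater", "less"), seed = 1,
                             parameter = NA_character_) {
  assert_that(!missing(direction),
              "`direction` must be chosen a priori ('greater' or 'less')")
  direction <- match.arg(direction)
  assert_that(length(x_values) >= 2, "need at least 2 X-linked values")
  assert_that(length(a_values) > length(x_values),
              "autosomal pool must be larger than the X set")
  assert_count(n_perm, "n_perm")

  n_x <- length(x_values)
  observed <- mean(x_values)
  null_means <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      mean(a_values[sample.int(length(a_values), n_x)])
    }, numeric(1))
  })
  extreme <- if (direction == "greater") null_means >= observed else null_means <= observed
  beaten <- if (direction == "greater") null_means < observed else null_means > observed
  structure(list(
    parameter = parameter, direction = direction,
    observed_mean_x = observed, n_x = n_x, n_perm = n_perm,
    null_means = null_means,
    empirical_p = (1 + sum(extreme)) / (n_perm + 1),
    significant = sum(beaten) > 0.95 * n_perm
  ), class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "<perm_test>%s observed mean(X) = %.4g vs %d null means (direction %s)\n  empirical p = %.4g%s\n",
    if (is.na(x$parameter)) "" else paste0(" ", x$parameter),
    x$observed_mean_x, x$n_perm, x$direction, x$empirical_p,
    if (x$significant) "  [distinct at the >95% rule]" else ""
  ))
  invisible(x)
}

#' @rdname permutation_test
#' @param x A `perm_test`.
#' @param ... Unused.
#' @export
tidy.perm_test <- function(x, ...) {
  tibble(
    parameter = x$parameter, direction = x$direction,
    observed_mean_x = x$observed_mean_x, null_mean = mean(x$null_means),
    n_x = x$n_x, n_perm = x$n_perm,
    empirical_p = x$empirical_p, significant = x$significant
  )
}

#' Tabulate credible-interval outlier calls by linkage
#'
#' Counts loci by linkage class (X / autosomal) and outlier category
#' (negative, zero i.e. neutral, positive) for each cline parameter, with a
#' totals row per parameter.
#'
#' @param estimates Per-locus estimates from [tidy()] on a `cline_fit` (needs
#'   `linkage`, `outlier_alpha`, `outlier_beta`).
#' @return Tibble: `parameter`, `type` (`"X"`, `"A"`, `"Total"`), `negative`,
#'   `zero`, `positive`.
#' @export
tabulate_outliers <- function(estimates) {
  assert_that(all(c("linkage", "outlier_alpha", "outlier_beta") %in% names(estimates)),
              "`estimates` must carry linkage and outlier columns")
  one <- function(par) {
    flag <- estimates[[paste0("outlier_", par)]]
    type <- ifelse(estimates$linkage == "X", "X", "A")
    rows <- lapply(c("X", "A"), function(tp) {
      f <- flag[type == tp]
      tibble(parameter = par, type = tp,
             negative = sum(f == "negative"), zero = sum(f == "none"),
             positive = sum(f == "positive"))
    })
    rows <- bind_rows(rows)
    bind_rows(rows, tibble(
      parameter = par, type = "Total",
      negative = sum(rows$negative), zero = sum(rows$zero),
      positive = sum(rows$positive)
    ))
  }
  bind_rows(one("beta"), one("alpha"))
}
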