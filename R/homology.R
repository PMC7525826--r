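#' Read pairwise-alignment records from a PAF file
#'
#' Parses the standard 12-column PAF produced by whole-genome aligners into a
#' tidy record table. Records whose target sequence name contains `"chrUn"`
#' (unplaced reference scaffolds) are dropped, since they cannot support a
#' chromosome assignment. Malformed lines fail with their line numbers.
#'
#' @param path Path to a PAF file.
#' @return Tibble with columns `query_id`, `query_length`, `query_start`,
#'   `query_end` (0-based half-open), `strand`, `target_chrom`,
#'   `target_length`, `target_start`, `target_end`, `matches`, `block_len`,
#'   `mapq`.
#' @export
read_paf <- function(path) {
  assert_that(file.exists(path), sprintf("PAF file not found: %s", path))
  cols <- c("query_id", "query_length", "query_start", "query_end", "strand",
            "target_chrom", "target_length", "target_start", "target_end",
            "matches", "block_len", "mapq")
  rec <- readr::read_tsv(
    path, col_names = FALSE, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (nrow(rec) == 0) {
    return(as_tibble(setNames(
      c(list(character()), rep(list(integer()), 3), list(character(), character()),
        rep(list(integer()), 6)),
      cols
    )))
  }
  assert_that(ncol(rec) >= 12, "PAF lines must have at least 12 columns")
  rec <- setNames(rec[, 1:12], cols)
  num_cols <- setdiff(cols, c("query_id", "strand", "target_chrom"))
  for (nm in num_cols) rec[[nm]] <- suppressWarnings(as.numeric(rec[[nm]]))
  bad <- which(
    Reduce(`|`, lapply(num_cols, function(nm) is.na(rec[[nm]]))) |
      rec$query_start < 0 | rec$target_start < 0 |
      rec$query_start >= rec$query_end | rec$target_start >= rec$target_end |
      rec$query_end > rec$query_length | rec$target_end > rec$target_length |
      !(rec$strand %in% c("+", "-"))
  )
  if (length(bad)) {
    abort(sprintf("malformed PAF line(s): %s",
                  paste(head(bad, 10), collapse = ", ")))
  }
  rec <- rec[!stringr::str_detect(rec$target_chrom, "chrUn"), , drop = FALSE]
  as_tibble(rec)
}

#' Assign contigs to reference chromosomes from alignment records
#'
#' Each alignment block covers `(query_end - query_start) / query_length` of
#' its contig; blocks below `min_coverage` are discarded. Among the passing
#' blocks of a contig, the chromosome of the block with the most matched bases
#' wins; a tie in matches across different chromosomes is reported as
#' `"ambiguous"` rather than silently resolved, and a contig with no passing
#' block is `"unmapped"`. With `coverage = "summed"`, per-chromosome coverage is
#' the summed block coverage instead.
#'
#' @param records Alignment record tibble from [read_paf()].
#' @param min_coverage Minimum query coverage per block, in `[0, 1]`.
#' @param coverage `"block"` (per-block, the default) or `"summed"`.
#' @return Tibble with one row per query: `query_id`, `assigned_chrom` (an
#'   actual chromosome, `"unmapped"`, or `"ambiguous"`), `best_coverage`,
#'   `target_start`, `target_end` (of the best block; NA when unassigned).
#' @export
assign_contigs <- function(records, min_coverage = 0.5,
                           coverage = c("block", "summed")) {
  coverage <- match.arg(coverage)
  assert_fraction(min_coverage, "min_coverage")
  if (nrow(records) == 0) {
    return(tibble(query_id = character(), assigned_chrom = character(),
                  best_coverage = numeric(), target_start = numeric(),
                  target_end = numeric()))
  }
  records |>
    mutate(block_coverage = (.data$query_end - .data$query_start) / .data$query_length) |>
    group_by(.data$query_id) |>
    dplyr::group_modify(~ assign_one(.x, min_coverage, coverage)) |>
    ungroup() |>
    arrange(.data$query_id)
}

assign_one <- function(rec, min_coverage, coverage) {
  unassigned <- function(status, cov) {
    tibble(assigned_chrom = status, best_coverage = cov,
           target_start = NA_real_, target_end = NA_real_)
  }
  if (coverage == "summed") {
    per_chrom <- rec |>
      group_by(.data$target_chrom) |>
      summarise(cov = sum(.data$block_coverage), .groups = "drop")
    pass_chroms <- per_chrom$target_chrom[per_chrom$cov >= min_coverage]
    pass <- rec[rec$target_chrom %in% pass_chroms, , drop = FALSE]
    if (nrow(pass) == 0) {
      return(unassigned("unmapped", max(per_chrom$cov)))
    }
    best_cov <- max(per_chrom$cov)
  } else {
    pass <- rec[rec$block_coverage >= min_coverage, , drop = FALSE]
    if (nrow(pass) == 0) {
      return(unassigned("unmapped", max(rec$block_coverage)))
    }
    best_cov <- max(pass$block_coverage)
  }
  top <- pass[pass$matches == max(pass$matches), , drop = FALSE]
  if (length(unique(top$target_chrom)) > 1L) {
    return(unassigned("ambiguous", best_cov))
  }
  tibble(assigned_chrom = top$target_chrom[1],
         best_coverage = best_cov,
         target_start = top$target_start[1], target_end = top$target_end[1])
}

#' Cross-tabulate contig classes against chromosome assignments
#'
#' Builds the validation crosstab of the sex-linkage screen: for each contig
#' class, how many contigs were assigned to the reference X versus autosomes,
#' and the validated X set -- contigs that are both female-biased (coverage
#' evidence) and homologous to the reference X (synteny evidence).
#'
#' @param classes `contig_class` tibble from [classify_contigs()].
#' @param assignments Assignment tibble from [assign_contigs()].
#' @param x_chrom Name of the reference X chromosome (must occur among the
#'   assignments or be a plausible chromosome name).
#' @return A list with `crosstab` (tibble: `class`, `n_contigs`, `n_mapped`,
#'   `n_x`, `n_autosome`, `pct_x_of_mapped`) and `validated_x` (character
#'   vector of contig ids).
#' @export
crosstab_linkage <- function(classes, assignments, x_chrom = "chrX") {
  assert_that(nrow(classes) > 0, "empty classification table")
  known <- setdiff(unique(assignments$assigned_chrom), c("unmapped", "ambiguous"))
  if (nrow(assignments) == 0) {
    warn("no chromosome assignments supplied; validated X set is empty")
  } else {
    assert_that(x_chrom %in% known || length(known) == 0,
                sprintf("chromosome `%s` absent from assignments", x_chrom))
  }
  joined <- classes |>
    left_join(assignments, by = c(contig = "query_id"))
  crosstab <- joined |>
    group_by(class) |>
    summarise(
      n_contigs = n(),
      n_mapped = sum(!is.na(.data$assigned_chrom) &
                       !.data$assigned_chrom %in% c("unmapped", "ambiguous")),
      n_x = sum(.data$assigned_chrom %in% x_chrom),
      n_autosome = .data$n_mapped - .data$n_x,
      pct_x_of_mapped = ifelse(.data$n_mapped > 0, 100 * .data$n_x / .data$n_mapped, NA_real_),
      .groups = "drop"
    )
  validated_x <- joined$contig[joined$class == "female-biased" &
                                 !is.na(joined$assigned_chrom) &
                                 joined$assigned_chrom %in% x_chrom]
  list(crosstab = crosstab, validated_x = validated_x)
}

#' Expand genomic intervals by a flank and merge overlaps
#'
#' Each interval is extended by `flank` bases on both sides (clamped to the
#' chromosome), and overlapping or bookended same-chromosome intervals are
#' merged, their member contigs unioned. Coordinates are 0-based half-open
#' internally; [format_region()] renders the 1-based inclusive form used in
#' reports.
#'
#' @param regions Tibble with `chrom`, `start`, `end` (0-based half-open) and
#'   optionally `members` (list-column or character of contributing contig
#'   ids).
#' @param flank Bases added to each side before merging (>= 0).
#' @param chrom_lengths Optional named vector of chromosome lengths used to
#'   clamp; intervals beyond a known length are an error.
#' @return Tibble `chrom`, `start`, `end`, `members` (list-column), sorted.
#' @examples
#' expand_and_merge(
#'   tibble::tibble(chrom = "chrX",
#'                  start = c(46475366, 47487522), end = c(47494965, 48488951)),
#'   flank = 0
#' )
#' @export
expand_and_merge <- function(regions, flank = 500000, chrom_lengths = NULL) {
  assert_positive(flank, "flank", strict = FALSE)
  assert_that(all(regions$start < regions$end), "regions must have start < end")
  if (!is.null(chrom_lengths)) {
    known <- regions$chrom %in% names(chrom_lengths)
    assert_that(all(known), "region on a chromosome absent from `chrom_lengths`")
    assert_that(all(regions$end <= chrom_lengths[regions$chrom]),
                "region extends past its chromosome end")
  }
  members <- if ("members" %in% names(regions)) {
    lapply(regions$members, as.character)
  } else {
    as.list(rep(NA_character_, nrow(regions)))
  }
  start <- pmax(0, regions$start - flank)
  end <- regions$end + flank
  if (!is.null(chrom_lengths)) end <- pmin(end, chrom_lengths[regions$chrom])

  out <- lapply(split(seq_len(nrow(regions)), regions$chrom), function(idx) {
    ir <- IRanges::IRanges(start = start[idx] + 1, end = end[idx]) # 1-based closed
    red <- IRanges::reduce(ir, min.gapwidth = 1L, with.revmap = TRUE)
    tibble(
      chrom = regions$chrom[idx[1]],
      start = IRanges::start(red) - 1,
      end = as.numeric(IRanges::end(red)),
      members = lapply(S4Vectors::mcols(red)$revmap, function(m) {
        sort(unique(stats::na.omit(unlist(members[idx[m]]))))
      })
    )
  })
  bind_rows(out) |> arrange(.data$chrom, .data$start)
}

#' Render a region in 1-based inclusive `chrom:start:end` report style
#'
#' @param regions Region tibble (0-based half-open `start`, `end`).
#' @return Character vector like `"X:46475367:47494965"`.
#' @export
format_region <- function(regions) {
  sprintf("%s:%d:%d", regions$chrom, as.integer(regions$start + 1),
          as.integer(regions$end))
}
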