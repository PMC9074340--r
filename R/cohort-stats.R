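# Integer percent display, round-half-away-from-zero (the convention used
# in the published prevalence tables, where 15/33 prints as 45).
percent_round <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Total-score histogram of a scored cohort
#'
#' Counts specimens at each total score 0..11.
#'
#' @param scored A scored specimen data.frame (see [score_specimens()]).
#' @param group Optional group label to subset on; `NULL` uses all rows.
#' @return A list of class `score_histogram` with elements `group`,
#'   `counts` (named integer vector over scores "0".."11") and `n`. An
#'   empty cohort gives an all-zero histogram with `n = 0`.
#' @export
score_histogram <- function(scored, group = NULL) {
  stopifnot(is.data.frame(scored), "total_score" %in% names(scored))
  if (!is.null(group)) scored <- scored[scored$group %in% group, , drop = FALSE]
  counts <- setNames(integer(12), as.character(0:11))
  if (nrow(scored) > 0L) {
    tab <- table(factor(scored$total_score, levels = 0:11))
    counts[] <- as.integer(tab)
  }
  structure(
    list(
      group = if (is.null(group)) "all" else paste(group, collapse = "+"),
      counts = counts,
      n = nrow(scored)
    ),
    class = "score_histogram"
  )
}

#' @export
print.score_histogram <- function(x, ...) {
  cat("Total-score histogram (", x$group, "), n = ", x$n, "\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Proportion of a cohort at or above a score cutoff
#'
#' @param scored A scored specimen data.frame (see [score_specimens()]).
#' @param cutoff Total-score cutoff in 0..11 (default 9).
#' @return A list with `count`, `n`, `fraction` and `percent` (integer,
#'   rounded half away from zero).
#' @examples
#' sc <- score_specimens(build_discovery_fixture())
#' proportion_at_or_above(sc, 9)  # 52 of 54, 96%
#' @export
proportion_at_or_above <- function(scored, cutoff = 9L) {
  stopifnot(is.data.frame(scored), "total_score" %in% names(scored))
  cutoff <- as.integer(cutoff)
  stopifnot(cutoff >= 0L, cutoff <= 11L)
  n <- nrow(scored)
  if (n == 0L) stop("cannot compute a proportion on an empty cohort", call. = FALSE)
  count <- sum(scored$total_score >= cutoff)
  list(
    count = count, n = n,
    fraction = count / n,
    percent = percent_round(100 * count / n)
  )
}

#' Per-marker pattern prevalence in a cohort
#'
#' Tabulates one marker's pattern calls over a cohort, with integer
#' percents in the published display convention.
#'
#' @param specimens A specimen data.frame (raw or scored).
#' @param marker One of [markers()].
#' @param group Optional group label(s) to subset on.
#' @return A list of class `pattern_prevalence` with `marker`, `group`,
#'   `counts` (named integer vector over the marker's admissible labels),
#'   `percent` and `n`.
#' @examples
#' fx <- build_discovery_fixture()
#' pattern_prevalence(fx, "LN5G2", group = "OVC")
#' @export
pattern_prevalence <- function(specimens, marker, group = NULL) {
  marker <- match_marker(marker)
  specimens <- as.data.frame(specimens)
  if (!is.null(group)) {
    specimens <- specimens[specimens$group %in% group, , drop = FALSE]
  }
  if (nrow(specimens) == 0L) {
    stop("no specimens in the requested group", call. = FALSE)
  }
  col <- marker_columns()[[marker]]
  calls <- specimens[[col]]
  if (any(is.na(calls))) {
    stop(
      "missing ", marker, " call(s) for specimen(s): ",
      paste(specimens$specimen_id[is.na(calls)], collapse = ", "),
      call. = FALSE
    )
  }
  calls <- canonicalize_label(marker, calls)
  counts <- table(factor(calls, levels = pattern_levels(marker)))
  counts <- setNames(as.integer(counts), names(counts))
  structure(
    list(
      marker = marker,
      group = if (is.null(group)) "all" else paste(group, collapse = "+"),
      counts = counts,
      percent = setNames(percent_round(100 * counts / sum(counts)), names(counts)),
      n = sum(counts)
    ),
    class = "pattern_prevalence"
  )
}

#' @export
print.pattern_prevalence <- function(x, ...) {
  cat(x$marker, " pattern prevalence (", x$group, "), n = ", x$n, "\n", sep = "")
  df <- data.frame(label = names(x$counts), n = x$counts, percent = x$percent)
  rownames(df) <- NULL
  print(df)
  invisible(x)
}

#' Collapse a prevalence to an in/out indicator
#'
#' Dichotomizes a pattern prevalence into "call in `target_labels`" versus
#' all other patterns, e.g. cytoplasmic Ln5g2 positivity = patterns
#' {B, C, D}.
#'
#' @param prevalence A [pattern_prevalence()] result.
#' @param target_labels Subset of the marker's admissible labels.
#' @return A list with `in_count`, `out_count`, `n`, `fraction`, `percent`.
#' @examples
#' fx <- build_discovery_fixture()
#' prev <- pattern_prevalence(fx, "LN5G2", group = "OVC")
#' collapse_to_indicator(prev, c("B", "C", "D"))  # 32 of 33, 97%
#' @export
collapse_to_indicator <- function(prevalence, target_labels) {
  stopifnot(inherits(prevalence, "pattern_prevalence"))
  target_labels <- canonicalize_label(prevalence$marker, target_labels)
  in_count <- sum(prevalence$counts[target_labels])
  list(
    in_count = in_count,
    out_count = prevalence$n - in_count,
    n = prevalence$n,
    fraction = in_count / prevalence$n,
    percent = percent_round(100 * in_count / prevalence$n)
  )
}

#' Compare a pattern proportion between two cohorts
#'
#' Collapses each cohort's prevalence of `target_labels` to a 2x2
#' contingency table (in/out x cohort) and applies the Pearson chi-square
#' test with 1 degree of freedom. No continuity correction by default,
#' matching the convention under which the published pattern-D comparison
#' (5/33 vs 12/21) gives p = 0.0012.
#'
#' @param prev_a,prev_b [pattern_prevalence()] results for the same marker
#'   in two cohorts.
#' @param target_labels Pattern labels defining the "positive" cell.
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return A list of class `contingency_result` with the 2x2 `table`,
#'   `chi_square`, `df` (1) and `p_value`.
#' @examples
#' fx <- build_discovery_fixture()
#' ovc <- pattern_prevalence(fx, "LN5G2", group = "OVC")
#' oscc <- pattern_prevalence(fx, "LN5G2", group = "OSCC")
#' compare_pattern_proportions(ovc, oscc, "D")
#' @export
compare_pattern_proportions <- function(prev_a, prev_b, target_labels,
                                        correct = FALSE) {
  stopifnot(
    inherits(prev_a, "pattern_prevalence"),
    inherits(prev_b, "pattern_prevalence")
  )
  if (prev_a$marker != prev_b$marker) {
    stop("prevalences are for different markers", call. = FALSE)
  }
  ia <- collapse_to_indicator(prev_a, target_labels)
  ib <- collapse_to_indicator(prev_b, target_labels)
  tab <- matrix(
    c(ia$in_count, ia$out_count, ib$in_count, ib$out_count),
    nrow = 2, byrow = TRUE,
    dimnames = list(
      cohort = c(prev_a$group, prev_b$group),
      pattern = c("in", "out")
    )
  )
  contingency_2x2(tab, correct = correct)
}

# Pearson chi-square on a 2x2 table with positive margins (df = 1).
contingency_2x2 <- function(tab, correct = FALSE) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate 2x2 table: a row or column margin is zero", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  structure(
    list(
      table = tab,
      chi_square = unname(ct$statistic),
      df = unname(ct$parameter),
      p_value = unname(ct$p.value),
      correct = correct
    ),
    class = "contingency_result"
  )
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("Pearson chi-square on 2x2 table",
    if (x$correct) " (Yates-corrected)" else "", "\n",
    sep = ""
  )
  print(x$table)
  cat(sprintf(
    "X-squared = %.4g, df = %d, p = %.2g\n",
    x$chi_square, x$df, x$p_value
  ))
  invisible(x)
}

#' General r x 2 chi-square on pattern counts
#'
#' Pearson chi-square over the full (uncollapsed) pattern distribution of
#' one marker in two cohorts. Provided for completeness; the published
#' comparisons all collapse to 2x2 first.
#'
#' @inheritParams compare_pattern_proportions
#' @param drop_empty Drop pattern labels unused in both cohorts (default
#'   `TRUE`; an all-zero row makes the statistic undefined).
#' @return A list of class `contingency_result` (df = number of retained
#'   labels minus 1).
#' @export
compare_pattern_distributions <- function(prev_a, prev_b, drop_empty = TRUE) {
  stopifnot(
    inherits(prev_a, "pattern_prevalence"),
    inherits(prev_b, "pattern_prevalence")
  )
  if (prev_a$marker != prev_b$marker) {
    stop("prevalences are for different markers", call. = FALSE)
  }
  tab <- cbind(prev_a$counts, prev_b$counts)
  colnames(tab) <- c(prev_a$group, prev_b$group)
  if (drop_empty) tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2L) {
    stop("fewer than two pattern labels with observations", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(
    list(
      table = tab,
      chi_square = unname(ct$statistic),
      df = unname(ct$parameter),
      p_value = unname(ct$p.value),
      correct = FALSE
    ),
    class = "contingency_result"
  )
}

#' Select a score cutoff retaining a minimum coverage
#'
#' Formalizes the by-inspection cutoff choice as: the largest cutoff `c`
#' in 0..11 such that the fraction of the (malignant) cohort with total
#' score >= `c` is at least `min_coverage`. With the default coverage of
#' 0.95 the discovery cohort yields 9.
#'
#' @param histogram A [score_histogram()] over a malignant cohort.
#' @param min_coverage Minimum fraction of the cohort the cutoff must
#'   retain (0 < min_coverage <= 1; default 0.95).
#' @return Integer cutoff in 0..11.
#' @examples
#' sc <- score_specimens(build_discovery_fixture())
#' select_cutoff(score_histogram(sc))  # 9
#' @export
select_cutoff <- function(histogram, min_coverage = 0.95) {
  stopifnot(inherits(histogram, "score_histogram"))
  stopifnot(min_coverage > 0, min_coverage <= 1)
  if (histogram$n == 0L) {
    stop("cannot select a cutoff from an empty histogram", call. = FALSE)
  }
  # fraction at or above c, for c = 0..11
  at_or_above <- rev(cumsum(rev(histogram$counts))) / histogram$n
  ok <- which(at_or_above >= min_coverage)
  if (length(ok) == 0L) return(0L)
  as.integer(max(ok) - 1L)  # index 1 corresponds to cutoff 0
}
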