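#' Build a two-rater call table
#'
#' @param specimen_id Character vector of specimen identifiers.
#' @param calls_a,calls_b Specimen data.frames (or lists of columns
#'   `ck13`, `ck17`, `ki67`, `ln5g2`) holding each observer's pattern
#'   calls, row-aligned with `specimen_id`.
#' @return A data.frame of class `rater_pairs` with columns `specimen_id`,
#'   `ck13_a`, `ck13_b`, ..., `ln5g2_a`, `ln5g2_b`.
#' @export
rater_pairs <- function(specimen_id, calls_a, calls_b) {
  specimen_id <- as.character(specimen_id)
  n <- length(specimen_id)
  out <- data.frame(specimen_id = specimen_id, stringsAsFactors = FALSE)
  cols <- marker_columns()
  for (m in markers()) {
    col <- cols[[m]]
    a <- calls_a[[col]]
    b <- calls_b[[col]]
    stopifnot(length(a) == n, length(b) == n)
    out[[paste0(col, "_a")]] <- canonicalize_label(m, a)
    out[[paste0(col, "_b")]] <- canonicalize_label(m, b)
  }
  class(out) <- c("rater_pairs", "data.frame")
  out
}

# extract (a, b) call vectors for one marker, optionally collapsing the
# two Ln5g2-negative labels or mapping labels to pattern scores
rater_calls <- function(pairs, marker, collapse_a = FALSE, on = "label") {
  col <- marker_columns()[[marker]]
  a <- canonicalize_label(marker, pairs[[paste0(col, "_a")]])
  b <- canonicalize_label(marker, pairs[[paste0(col, "_b")]])
  if (any(is.na(a)) || any(is.na(b))) {
    stop("missing ", marker, " call(s) in rater table", call. = FALSE)
  }
  if (on == "score") {
    # categories with equal pattern scores merge
    a <- as.character(pattern_score(marker, a))
    b <- as.character(pattern_score(marker, b))
    levels <- as.character(sort(unique(pattern_score(marker, pattern_levels(marker)))))
    return(list(a = a, b = b, levels = levels))
  }
  levels <- pattern_levels(marker)
  if (collapse_a && marker == "LN5G2") {
    a[a %in% c("A1", "A2")] <- "A"
    b[b %in% c("A1", "A2")] <- "A"
    levels <- c("A", "B", "C", "D")
  }
  list(a = unname(a), b = unname(b), levels = levels)
}

#' Cohen's kappa for one marker's pattern calls
#'
#' Unweighted (nominal-category) Cohen's kappa between two observers'
#' pattern calls for a single marker, computed over the marker's full
#' admissible label set: labels neither observer used contribute zero
#' marginal mass, so they do not change the statistic but keep the
#' cross-table shape stable across cohorts.
#'
#' @param pairs A [rater_pairs()] data.frame.
#' @param marker One of [markers()].
#' @param collapse_a For Ln5g2, merge the two negative labels A1 and A2
#'   into a single category "A" before computing kappa (default `FALSE`).
#' @param on `"label"` (default) computes kappa on pattern labels;
#'   `"score"` on pattern scores (categories with equal scores merged).
#' @return A list of class `kappa_result` with `marker`, `n`,
#'   `observed_agreement`, `expected_agreement`, `kappa` and the
#'   cross-table `table`.
#' @examples
#' fx <- build_validation_fixture()
#' rp <- generate_rater_pairs(fx, disagreement_rate = 0.1, seed = 1)
#' cohens_kappa(rp, "CK13")
#' @export
cohens_kappa <- function(pairs, marker, collapse_a = FALSE,
                         on = c("label", "score")) {
  on <- match.arg(on)
  marker <- match_marker(marker)
  if (nrow(pairs) < 1L) stop("need at least one rated specimen", call. = FALSE)
  rc <- rater_calls(pairs, marker, collapse_a = collapse_a, on = on)
  tab <- table(
    factor(rc$a, levels = rc$levels),
    factor(rc$b, levels = rc$levels),
    dnn = c("rater_a", "rater_b")
  )
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1) {
    # both raters constant: identical constant => perfect agreement
    if (po < 1) {
      stop("degenerate marginals: expected agreement is 1 with imperfect observed agreement", call. = FALSE)
    }
    kappa <- 1
  } else {
    kappa <- (po - pe) / (1 - pe)
  }
  structure(
    list(
      marker = marker, n = n,
      observed_agreement = po, expected_agreement = pe,
      kappa = kappa, table = tab
    ),
    class = "kappa_result"
  )
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf(
    "Cohen's kappa for %s: %.3f (observed %.3f, expected %.3f, n = %d)\n",
    x$marker, x$kappa, x$observed_agreement, x$expected_agreement, x$n
  ))
  invisible(x)
}

#' Per-marker kappa panel
#'
#' [cohens_kappa()] applied to all four markers.
#'
#' @inheritParams cohens_kappa
#' @return A data.frame with one row per marker: `marker`, `n`,
#'   `observed_agreement`, `expected_agreement`, `kappa`.
#' @export
kappa_panel <- function(pairs, collapse_a = FALSE, on = c("label", "score")) {
  on <- match.arg(on)
  rows <- lapply(markers(), function(m) {
    k <- cohens_kappa(pairs, m, collapse_a = collapse_a, on = on)
    data.frame(
      marker = m, n = k$n,
      observed_agreement = k$observed_agreement,
      expected_agreement = k$expected_agreement,
      kappa = k$kappa
    )
  })
  do.call(rbind, rows)
}

#' Binary benign/malignant agreement between two observers
#'
#' Scores each observer's complete call set per specimen and reports the
#' fraction of specimens on which the two observers agree about the
#' binary diagnosis `total_score >= cutoff`. Disagreements confined to
#' labels with equal pattern scores (e.g. Ki-67 B vs C) cannot change a
#' total and therefore never lower this fraction.
#'
#' @param pairs A [rater_pairs()] data.frame with complete calls for all
#'   four markers.
#' @param cutoff Total-score cutoff (default 9).
#' @return Fraction in [0, 1].
#' @export
binary_diagnosis_agreement <- function(pairs, cutoff = 9L) {
  if (nrow(pairs) < 1L) {
    stop("need at least one rated specimen", call. = FALSE)
  }
  totals <- function(suffix) {
    sp <- specimen_table(
      pairs$specimen_id, "rated",
      ck13 = pairs[[paste0("ck13_", suffix)]],
      ck17 = pairs[[paste0("ck17_", suffix)]],
      ki67 = pairs[[paste0("ki67_", suffix)]],
      ln5g2 = pairs[[paste0("ln5g2_", suffix)]]
    )
    score_specimens(sp)$total_score
  }
  ta <- totals("a")
  tb <- totals("b")
  mean((ta >= cutoff) == (tb >= cutoff))
}
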