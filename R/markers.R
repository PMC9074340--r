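#' The four-marker panel
#'
#' Returns the identifiers of the four immunohistochemistry markers of the
#' scoring panel, in canonical order: `"CK13"`, `"CK17"`, `"KI67"`,
#' `"LN5G2"`. These are the only markers the package accepts.
#'
#' @return Character vector of length 4.
#' @examples
#' markers()
#' @export
markers <- function() {
  c("CK13", "CK17", "KI67", "LN5G2")
}

# lowercase column names used in specimen tables, in marker order
marker_columns <- function() {
  c(CK13 = "ck13", CK17 = "ck17", KI67 = "ki67", LN5G2 = "ln5g2")
}

#' Admissible staining-pattern labels for a marker
#'
#' CK13, CK17 and Ki-67 patterns are called A, B or C. Ln5g2 has five
#' labels: A1 (no expression) and A2 (expression on an intact basement
#' membrane only) are biologically distinct observations that share pattern
#' score 0; B, C and D grade the extent of cytoplasmic staining at the
#' tumor-stroma interface (<10%, 10-50%, >50% of interface cells).
#'
#' @param marker One of [markers()].
#' @return Character vector of admissible labels.
#' @examples
#' pattern_levels("LN5G2")
#' @export
pattern_levels <- function(marker) {
  marker <- match_marker(marker)
  switch(marker,
    CK13 = c("A", "B", "C"),
    CK17 = c("A", "B", "C"),
    KI67 = c("A", "B", "C"),
    LN5G2 = c("A1", "A2", "B", "C", "D")
  )
}

match_marker <- function(marker) {
  if (length(marker) != 1L || is.na(marker)) {
    stop("`marker` must be a single marker name", call. = FALSE)
  }
  m <- toupper(as.character(marker))
  # tolerate common field spellings
  m <- switch(m,
    "KI-67" = "KI67",
    "LN5GAMMA2" = "LN5G2",
    m
  )
  if (!m %in% markers()) {
    stop(
      "unknown marker '", marker, "'; expected one of ",
      paste(markers(), collapse = ", "),
      call. = FALSE
    )
  }
  m
}

#' Canonicalize a vector of pattern labels for one marker
#'
#' Labels are case-insensitive on input and canonicalized to upper case.
#' Inadmissible labels raise an error naming the offending values.
#'
#' @param marker One of [markers()].
#' @param label Character vector of pattern labels.
#' @return Character vector of canonical labels.
#' @export
canonicalize_label <- function(marker, label) {
  marker <- match_marker(marker)
  lab <- toupper(trimws(as.character(label)))
  admissible <- pattern_levels(marker)
  bad <- setdiff(unique(lab[!is.na(lab)]), admissible)
  if (length(bad) > 0L) {
    stop(
      "invalid pattern label(s) for ", marker, ": ",
      paste(sQuote(bad), collapse = ", "),
      " (admissible: ", paste(admissible, collapse = ", "), ")",
      call. = FALSE
    )
  }
  lab
}

#' The pattern-score table
#'
#' The mapping from (marker, pattern label) to integer pattern score.
#' Differentiation markers CK13 and CK17 score 0/1/2 for patterns A/B/C;
#' the proliferation marker Ki-67 scores 0 for pattern A and 3 for the
#' oncogenic patterns B and C; the invasion marker Ln5g2 scores 0 for the
#' negative patterns A1/A2 and 4 for any cytoplasmic positivity (B, C, D).
#' Invasion carries the largest weight, followed by proliferation, then
#' differentiation, so the tiers of biological evidence are separable in
#' the total.
#'
#' @return A data.frame with columns `marker`, `label`, `score`, one row
#'   per admissible (marker, label) pair (12 rows).
#' @examples
#' pattern_score_table()
#' @export
pattern_score_table <- function() {
  tab <- rbind(
    data.frame(marker = "CK13", label = c("A", "B", "C"), score = c(0L, 1L, 2L)),
    data.frame(marker = "CK17", label = c("A", "B", "C"), score = c(0L, 1L, 2L)),
    data.frame(marker = "KI67", label = c("A", "B", "C"), score = c(0L, 3L, 3L)),
    data.frame(
      marker = "LN5G2", label = c("A1", "A2", "B", "C", "D"),
      score = c(0L, 0L, 4L, 4L, 4L)
    )
  )
  tab
}

#' Pattern score for a marker and pattern label
#'
#' Looks up the integer pattern score of a staining-pattern call.
#' Vectorized over `label`.
#'
#' @param marker One of [markers()].
#' @param label Pattern label(s), case-insensitive.
#' @return Integer vector of pattern scores.
#' @examples
#' pattern_score("LN5G2", "D")  # 4
#' pattern_score("CK13", "A")   # 0
#' pattern_score("KI67", c("A", "B", "C"))
#' @export
pattern_score <- function(marker, label) {
  marker <- match_marker(marker)
  lab <- canonicalize_label(marker, label)
  tab <- pattern_score_table()
  tab <- tab[tab$marker == marker, ]
  out <- tab$score[match(lab, tab$label)]
  names(out) <- NULL
  out
}
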