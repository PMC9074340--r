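#' Build a specimen table
#'
#' Convenience constructor for the specimen data.frame the scoring
#' functions consume: one row per specimen with columns `specimen_id`,
#' `group`, `ck13`, `ck17`, `ki67`, `ln5g2`. Labels are canonicalized
#' (upper case) and validated against each marker's admissible set; `NA`
#' marks a missing call.
#'
#' @param specimen_id Character vector of unique specimen identifiers.
#' @param group Diagnosis/group label per specimen (e.g. "OVC", "OSCC",
#'   "papilloma"); recycled if length 1.
#' @param ck13,ck17,ki67,ln5g2 Pattern calls per marker.
#' @return A data.frame of class `specimen_table`.
#' @examples
#' specimen_table("s1", "OSCC", ck13 = "C", ck17 = "C", ki67 = "B", ln5g2 = "D")
#' @export
specimen_table <- function(specimen_id, group, ck13, ck17, ki67, ln5g2) {
  specimen_id <- as.character(specimen_id)
  n <- length(specimen_id)
  if (anyDuplicated(specimen_id)) {
    stop(
      "duplicate specimen_id: ",
      paste(unique(specimen_id[duplicated(specimen_id)]), collapse = ", "),
      call. = FALSE
    )
  }
  if (length(group) == 1L) group <- rep(group, n)
  calls <- list(ck13 = ck13, ck17 = ck17, ki67 = ki67, ln5g2 = ln5g2)
  cols <- marker_columns()
  for (m in markers()) {
    v <- calls[[cols[[m]]]]
    if (length(v) == 1L) v <- rep(v, n)
    stopifnot(length(v) == n)
    calls[[cols[[m]]]] <- canonicalize_label(m, v)
  }
  out <- data.frame(
    specimen_id = specimen_id,
    group = as.character(group),
    ck13 = calls$ck13, ck17 = calls$ck17,
    ki67 = calls$ki67, ln5g2 = calls$ln5g2,
    stringsAsFactors = FALSE
  )
  class(out) <- c("specimen_table", "data.frame")
  out
}

as_specimen_table <- function(df) {
  req <- c("specimen_id", "group", marker_columns())
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    stop(
      "specimen table lacks column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  specimen_table(
    df$specimen_id, df$group,
    ck13 = df$ck13, ck17 = df$ck17, ki67 = df$ki67, ln5g2 = df$ln5g2
  )
}

#' Risk-tier policy
#'
#' The classification policy applied to total scores. The defaults encode
#' the published rule: a total score at or above `cutoff` (9) flags
#' immediate risk of oral squamous malignancy. Below the cutoff, an
#' Ln5g2-negative specimen whose differentiation/proliferation patterns
#' still sum to `alert_threshold` (5) or more may simply have missed the
#' invasion front in a small biopsy, so it is flagged for re-sampling or
#' close follow-up; an Ln5g2-positive specimen in the 5-8 band is reported
#' as indeterminate; everything else is low risk.
#'
#' @param cutoff Total score at or above which a specimen is classified
#'   `IMMEDIATE_RISK` (0-11, default 9).
#' @param alert_threshold Total score at or above which a sub-cutoff
#'   specimen leaves the `LOW` tier (0-11, default 5; must be <= cutoff).
#' @return A list of class `risk_policy`.
#' @export
risk_policy <- function(cutoff = 9L, alert_threshold = 5L) {
  cutoff <- as.integer(cutoff)
  alert_threshold <- as.integer(alert_threshold)
  if (is.na(cutoff) || cutoff < 0L || cutoff > 11L) {
    stop("`cutoff` must be in 0..11", call. = FALSE)
  }
  if (is.na(alert_threshold) || alert_threshold < 0L || alert_threshold > 11L) {
    stop("`alert_threshold` must be in 0..11", call. = FALSE)
  }
  if (alert_threshold > cutoff) {
    stop("`alert_threshold` must not exceed `cutoff`", call. = FALSE)
  }
  structure(
    list(cutoff = cutoff, alert_threshold = alert_threshold),
    class = "risk_policy"
  )
}

#' Risk-tier labels
#'
#' @return Character vector of the four risk tiers, from most to least
#'   actionable.
#' @export
risk_tiers <- function() {
  c("IMMEDIATE_RISK", "ALERT_RESAMPLE", "INDETERMINATE", "LOW")
}

#' Classify total scores into risk tiers
#'
#' Vectorized classification of a total score given the specimen's Ln5g2
#' pattern score. `IMMEDIATE_RISK` iff `total_score >= cutoff`;
#' `ALERT_RESAMPLE` iff Ln5g2 is negative (score 0) and the total reaches
#' the alert threshold; `INDETERMINATE` iff Ln5g2 is positive (score 4)
#' and the total is in `[alert_threshold, cutoff - 1]`; `LOW` otherwise.
#'
#' @param total_score Integer vector in 0..11.
#' @param ln5g2_score Integer vector in {0, 4}, recycled if length 1.
#' @param policy A [risk_policy()].
#' @return Factor with levels [risk_tiers()].
#' @examples
#' classify_risk(11, 4)  # IMMEDIATE_RISK
#' classify_risk(7, 0)   # ALERT_RESAMPLE
#' classify_risk(8, 4)   # INDETERMINATE
#' classify_risk(0, 0)   # LOW
#' @export
classify_risk <- function(total_score, ln5g2_score, policy = risk_policy()) {
  stopifnot(inherits(policy, "risk_policy"))
  total_score <- as.integer(total_score)
  ln5g2_score <- as.integer(ln5g2_score)
  if (length(ln5g2_score) == 1L) {
    ln5g2_score <- rep(ln5g2_score, length(total_score))
  }
  stopifnot(length(ln5g2_score) == length(total_score))
  if (any(is.na(total_score)) || any(is.na(ln5g2_score))) {
    stop("scores must not be NA", call. = FALSE)
  }
  if (any(total_score < 0L | total_score > 11L)) {
    stop("`total_score` must be in 0..11", call. = FALSE)
  }
  if (any(!ln5g2_score %in% c(0L, 4L))) {
    stop("`ln5g2_score` must be 0 or 4", call. = FALSE)
  }
  if (any(ln5g2_score > total_score)) {
    stop("invariant violation: ln5g2_score exceeds total_score", call. = FALSE)
  }
  tier <- rep("LOW", length(total_score))
  alert_band <- total_score >= policy$alert_threshold & total_score < policy$cutoff
  tier[alert_band & ln5g2_score == 0L] <- "ALERT_RESAMPLE"
  tier[alert_band & ln5g2_score == 4L] <- "INDETERMINATE"
  tier[total_score >= policy$cutoff] <- "IMMEDIATE_RISK"
  factor(tier, levels = risk_tiers())
}

#' Score a specimen table
#'
#' Maps each specimen's four pattern calls to per-marker pattern scores,
#' sums them to the total score (0-11) and assigns a risk tier. This is
#' the central operation of the scoring system.
#'
#' By default every marker must be called; specimens with missing calls
#' raise an error naming the specimen and the absent markers. With
#' `missing = "lower_bound"` a missing call scores 0 and the specimen is
#' flagged in the `lower_bound` column: its total is then a lower bound on
#' the true total (useful when a stain failed on a real biopsy), and its
#' risk tier is computed from that bound.
#'
#' @param specimens A specimen data.frame with columns `specimen_id`,
#'   `group`, `ck13`, `ck17`, `ki67`, `ln5g2` (see [specimen_table()]).
#' @param policy A [risk_policy()].
#' @param missing `"error"` (default) or `"lower_bound"`.
#' @return The input data.frame with added columns `score_ck13`,
#'   `score_ck17`, `score_ki67`, `score_ln5g2`, `total_score`,
#'   `risk_tier`, and `lower_bound` (logical).
#' @examples
#' sp <- specimen_table(c("s1", "s2"), "OSCC",
#'   ck13 = c("C", "B"), ck17 = c("C", "B"),
#'   ki67 = c("C", "B"), ln5g2 = c("D", "B")
#' )
#' score_specimens(sp)
#' @export
score_specimens <- function(specimens, policy = risk_policy(),
                            missing = c("error", "lower_bound")) {
  missing <- match.arg(missing)
  specimens <- as_specimen_table(specimens)
  cols <- marker_columns()

  if (missing == "error") {
    incomplete <- vapply(seq_len(nrow(specimens)), function(i) {
      any(is.na(unlist(specimens[i, cols], use.names = FALSE)))
    }, logical(1))
    if (any(incomplete)) {
      msgs <- vapply(which(incomplete), function(i) {
        absent <- markers()[is.na(unlist(specimens[i, cols], use.names = FALSE))]
        paste0(specimens$specimen_id[i], " (missing ", paste(absent, collapse = ", "), ")")
      }, character(1))
      stop(
        "incomplete specimen record(s): ", paste(msgs, collapse = "; "),
        "; use missing = \"lower_bound\" to score anyway",
        call. = FALSE
      )
    }
  }

  out <- as.data.frame(specimens)
  any_missing <- rep(FALSE, nrow(out))
  for (m in markers()) {
    lab <- out[[cols[[m]]]]
    sc <- rep(NA_integer_, length(lab))
    ok <- !is.na(lab)
    if (any(ok)) sc[ok] <- pattern_score(m, lab[ok])
    any_missing <- any_missing | !ok
    sc[!ok] <- 0L
    out[[paste0("score_", cols[[m]])]] <- sc
  }
  out$total_score <- out$score_ck13 + out$score_ck17 + out$score_ki67 + out$score_ln5g2
  out$risk_tier <- classify_risk(out$total_score, out$score_ln5g2, policy)
  out$lower_bound <- any_missing
  class(out) <- c("scored_specimens", "data.frame")
  out
}

#' Total score of a single specimen
#'
#' Convenience wrapper around [score_specimens()] for one specimen given
#' as four pattern calls.
#'
#' @param ck13,ck17,ki67,ln5g2 Single pattern calls.
#' @param policy A [risk_policy()].
#' @return A one-row scored data.frame (see [score_specimens()]).
#' @examples
#' total_score(ck13 = "C", ck17 = "C", ki67 = "C", ln5g2 = "D")$total_score  # 11
#' @export
total_score <- function(ck13, ck17, ki67, ln5g2, policy = risk_policy()) {
  sp <- specimen_table("specimen", "unspecified",
    ck13 = ck13, ck17 = ck17, ki67 = ki67, ln5g2 = ln5g2
  )
  score_specimens(sp, policy = policy)
}

#' All admissible pattern combinations
#'
#' Enumerates the full 3 x 3 x 3 x 5 = 135 grid of admissible pattern-call
#' combinations as a specimen table (ids `combo_001` ... `combo_135`),
#' mainly for exhaustive structural checks of the score scale.
#'
#' @return A `specimen_table` with 135 rows, group `"grid"`.
#' @export
all_pattern_combinations <- function() {
  grid <- expand.grid(
    ck13 = pattern_levels("CK13"),
    ck17 = pattern_levels("CK17"),
    ki67 = pattern_levels("KI67"),
    ln5g2 = pattern_levels("LN5G2"),
    stringsAsFactors = FALSE,
    KEEP.OUT.ATTRS = FALSE
  )
  specimen_table(
    sprintf("combo_%03d", seq_len(nrow(grid))), "grid",
    ck13 = grid$ck13, ck17 = grid$ck17, ki67 = grid$ki67, ln5g2 = grid$ln5g2
  )
}
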