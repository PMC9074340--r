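#' Paired tumor-versus-normal log-expression test
#'
#' Paired t-test on log-transformed expression values for one gene
#' measured in matched normal/tumor tissue per patient. Values must be
#' strictly positive before the log transform; supply a `pseudocount` to
#' shift data containing zeros.
#'
#' The log base (default 2) only rescales the mean log-difference and the
#' effect estimate; t and p are base-invariant. If the per-patient
#' log-differences have zero variance but a non-zero mean (an exact
#' constant fold-change), the t statistic is infinite; the result then
#' carries `zero_variance = TRUE` and reports `p_value = 0` by
#' convention. If all differences are exactly zero the direction is
#' `"flat"` with `t = 0`, `p = 1`.
#'
#' @param normal,tumor Numeric vectors of positive expression values,
#'   aligned per patient (length >= 2).
#' @param gene Optional gene name carried into the result.
#' @param base Log base (default 2).
#' @param pseudocount Non-negative constant added to both vectors before
#'   the log transform (default 0; zeros are an error without it).
#' @return A list of class `paired_log_t` with `gene`, `n`,
#'   `mean_log_diff` (tumor minus normal, in log-`base` units), `t`,
#'   `df`, `p_value`, `direction` (`"up"`, `"down"` or `"flat"`) and
#'   `zero_variance`.
#' @examples
#' paired_log_t_test(normal = c(1, 2, 4, 8), tumor = c(2, 8, 8, 32))
#' @export
paired_log_t_test <- function(normal, tumor, gene = NA_character_,
                              base = 2, pseudocount = 0) {
  normal <- as.numeric(normal) + pseudocount
  tumor <- as.numeric(tumor) + pseudocount
  if (length(normal) != length(tumor)) {
    stop("normal and tumor vectors must be paired (equal length)", call. = FALSE)
  }
  n <- length(normal)
  if (n < 2L) stop("need at least 2 patient pairs", call. = FALSE)
  if (any(!is.finite(normal)) || any(!is.finite(tumor))) {
    stop("expression values must be finite", call. = FALSE)
  }
  if (any(normal <= 0) || any(tumor <= 0)) {
    stop(
      "non-positive expression values cannot be log-transformed; ",
      "supply a pseudocount if zeros are expected",
      call. = FALSE
    )
  }
  d <- log(tumor, base = base) - log(normal, base = base)
  mean_d <- mean(d)
  zero_var <- isTRUE(all.equal(sd(d), 0)) || sd(d) == 0
  if (zero_var) {
    if (mean_d == 0) {
      t_stat <- 0; p <- 1
    } else {
      t_stat <- sign(mean_d) * Inf; p <- 0
    }
    df <- n - 1L
  } else {
    tt <- t.test(log(tumor, base = base), log(normal, base = base), paired = TRUE)
    t_stat <- unname(tt$statistic)
    df <- unname(tt$parameter)
    p <- tt$p.value
  }
  direction <- if (mean_d > 0) "up" else if (mean_d < 0) "down" else "flat"
  structure(
    list(
      gene = gene, n = n, base = base,
      mean_log_diff = mean_d,
      t = t_stat, df = df, p_value = p,
      direction = direction, zero_variance = zero_var
    ),
    class = "paired_log_t"
  )
}

#' @export
print.paired_log_t <- function(x, ...) {
  cat(sprintf(
    "Paired log%g t-test%s: mean log-diff (T-N) = %.3f, t = %.3f, df = %g, p = %.3g [%s]%s\n",
    x$base,
    if (is.na(x$gene)) "" else paste0(" for ", x$gene),
    x$mean_log_diff, x$t, x$df, x$p_value, x$direction,
    if (x$zero_variance) " (zero-variance differences)" else ""
  ))
  invisible(x)
}

#' Run the paired-expression panel over a long table
#'
#' Applies [paired_log_t_test()] per gene to a long-format expression
#' table (columns `gene`, `patient_id`, `normal`, `tumor`), as used for
#' the four genes matching the IHC panel: KRT13, KRT17, MKI67, LAMC2.
#' No multiple-testing adjustment is applied. A gene whose test fails
#' (e.g. non-positive values) yields an `NA` row with the error message
#' in `note` rather than aborting the panel.
#'
#' @param expression Long data.frame with columns `gene`, `patient_id`,
#'   `normal`, `tumor`.
#' @param base,pseudocount Passed to [paired_log_t_test()].
#' @return A data.frame with one row per gene: `gene`, `n`,
#'   `mean_log_diff`, `t`, `p_value`, `direction`, `zero_variance`,
#'   `note`.
#' @examples
#' expr <- generate_expression_pairs(
#'   fold_changes = c(KRT13 = 0.5, KRT17 = 2, MKI67 = 2, LAMC2 = 2),
#'   n_patients = 40, noise_sd = 0.25, seed = 7
#' )
#' run_expression_panel(expr)
#' @export
run_expression_panel <- function(expression, base = 2, pseudocount = 0) {
  req <- c("gene", "patient_id", "normal", "tumor")
  missing_cols <- setdiff(req, names(expression))
  if (length(missing_cols) > 0L) {
    stop(
      "expression table lacks column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  genes <- unique(as.character(expression$gene))
  rows <- lapply(genes, function(g) {
    sub <- expression[expression$gene == g, , drop = FALSE]
    res <- tryCatch(
      paired_log_t_test(sub$normal, sub$tumor,
        gene = g, base = base, pseudocount = pseudocount
      ),
      error = function(e) conditionMessage(e)
    )
    if (is.character(res)) {
      data.frame(
        gene = g, n = nrow(sub), mean_log_diff = NA_real_,
        t = NA_real_, p_value = NA_real_, direction = NA_character_,
        zero_variance = NA, note = res
      )
    } else {
      data.frame(
        gene = g, n = res$n, mean_log_diff = res$mean_log_diff,
        t = res$t, p_value = res$p_value, direction = res$direction,
        zero_variance = res$zero_variance, note = ""
      )
    }
  })
  if (length(rows) == 0L) {
    return(data.frame(
      gene = character(), n = integer(), mean_log_diff = numeric(),
      t = numeric(), p_value = numeric(), direction = character(),
      zero_variance = logical(), note = character()
    ))
  }
  do.call(rbind, rows)
}
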