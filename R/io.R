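#' Read a specimen table from CSV/TSV
#'
#' Expects a header row with columns `specimen_id`, `group`, `ck13`,
#' `ck17`, `ki67`, `ln5g2`. The delimiter is sniffed from the header line
#' (comma vs tab) unless given. Labels are case-insensitive and
#' canonicalized; an inadmissible label raises an error naming the row
#' and column; duplicate specimen ids are an error.
#'
#' @param path Path to the file.
#' @param delimiter `NULL` (sniff), `","` or `"\t"`.
#' @return A `specimen_table` data.frame.
#' @export
read_specimen_table <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delimiter)) {
    header <- readLines(path, n = 1L)
    delimiter <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(
    path,
    header = TRUE, sep = delimiter, colClasses = "character",
    check.names = TRUE, stringsAsFactors = FALSE,
    na.strings = c("", "NA"), fileEncoding = "UTF-8"
  )
  names(df) <- tolower(names(df))
  req <- c("specimen_id", "group", marker_columns())
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    stop(
      "input lacks column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(df$specimen_id)) {
    stop(
      "duplicate specimen_id: ",
      paste(unique(df$specimen_id[duplicated(df$specimen_id)]), collapse = ", "),
      call. = FALSE
    )
  }
  # validate per row so errors carry the file location
  for (m in markers()) {
    col <- marker_columns()[[m]]
    v <- df[[col]]
    for (i in seq_along(v)) {
      if (is.na(v[i])) next
      ok <- tryCatch(
        {
          canonicalize_label(m, v[i])
          TRUE
        },
        error = function(e) conditionMessage(e)
      )
      if (!isTRUE(ok)) {
        stop(
          "parse error at data row ", i, ", column '", col, "': ", ok,
          call. = FALSE
        )
      }
    }
  }
  specimen_table(
    df$specimen_id, df$group,
    ck13 = df$ck13, ck17 = df$ck17, ki67 = df$ki67, ln5g2 = df$ln5g2
  )
}

#' Write a (scored) specimen table
#'
#' @param x A specimen or scored-specimen data.frame.
#' @param path Output path.
#' @param delimiter `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_specimen_table <- function(x, path, delimiter = ",") {
  df <- as.data.frame(x)
  if ("risk_tier" %in% names(df)) df$risk_tier <- as.character(df$risk_tier)
  utils::write.table(
    df, path,
    sep = delimiter, row.names = FALSE, quote = FALSE,
    fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' Pipeline configuration
#'
#' @param input Path to a specimen CSV/TSV, or a specimen data.frame.
#' @param output_dir Directory for the report files (created if needed).
#' @param delimiter Input delimiter (`NULL` = sniff).
#' @param cutoff Total-score cutoff for `IMMEDIATE_RISK` (default 9).
#' @param alert_threshold Lower tier bound (default 5).
#' @param min_coverage Coverage used by [select_cutoff()] (default 0.95).
#' @param continuity_correction Yates correction for the 2x2 chi-square
#'   comparisons (default `FALSE`).
#' @param compare_groups Length-2 character vector of group labels to
#'   compare pattern proportions between, or `NULL` to skip.
#' @param format `"json"`, `"tsv"` or both.
#' @param seed Integer seed recorded in the report (the scoring pipeline
#'   itself is deterministic; the seed governs any simulation step).
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(input, output_dir = NULL, delimiter = NULL,
                            cutoff = 9L, alert_threshold = 5L,
                            min_coverage = 0.95,
                            continuity_correction = FALSE,
                            compare_groups = NULL,
                            format = c("json", "tsv"),
                            seed = 1L) {
  format <- match.arg(format, several.ok = TRUE)
  policy <- risk_policy(cutoff, alert_threshold)  # validates the bounds
  stopifnot(min_coverage > 0, min_coverage <= 1)
  if (!is.null(compare_groups) && length(compare_groups) != 2L) {
    stop("`compare_groups` must name exactly two groups", call. = FALSE)
  }
  structure(
    list(
      input = input, output_dir = output_dir, delimiter = delimiter,
      policy = policy, min_coverage = min_coverage,
      continuity_correction = continuity_correction,
      compare_groups = compare_groups,
      format = format, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

report_schema_version <- "1.0"

#' Run the scoring pipeline
#'
#' Reads (or takes) a specimen table, scores every specimen, and builds a
#' report bundle: the scored table, per-group total-score histograms and
#' pattern prevalences, the proportion at or above the cutoff per group,
#' and (optionally) per-marker 2x2 pattern comparisons between two
#' groups. With an `output_dir` the bundle is written as
#' `scored.csv` plus `report.json` and/or `report.tsv`; outputs are
#' deterministic given the same inputs and configuration.
#'
#' @param config A [pipeline_config()].
#' @return The report bundle, invisibly a list with elements `scored`,
#'   `summary`, and `files` (paths written, if any).
#' @examples
#' cfg <- pipeline_config(build_discovery_fixture())
#' rep <- run_pipeline(cfg)
#' rep$summary$groups$OVC$at_or_above$count
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  specimens <- if (is.character(config$input)) {
    read_specimen_table(config$input, config$delimiter)
  } else {
    as_specimen_table(config$input)
  }
  if (nrow(specimens) == 0L) {
    stop("input specimen table is empty", call. = FALSE)
  }
  scored <- score_specimens(specimens, policy = config$policy)

  groups <- unique(scored$group)
  group_summaries <- lapply(groups, function(g) {
    sub <- scored[scored$group == g, , drop = FALSE]
    hist <- score_histogram(sub)
    prev <- lapply(markers(), function(m) {
      p <- pattern_prevalence(sub, m)
      list(counts = as.list(p$counts), percent = as.list(p$percent), n = p$n)
    })
    names(prev) <- markers()
    list(
      n = nrow(sub),
      histogram = as.list(hist$counts),
      at_or_above = proportion_at_or_above(sub, config$policy$cutoff),
      risk_tiers = as.list(table(sub$risk_tier)),
      prevalence = prev
    )
  })
  names(group_summaries) <- groups

  comparisons <- NULL
  if (!is.null(config$compare_groups)) {
    ga <- config$compare_groups[1]
    gb <- config$compare_groups[2]
    comparisons <- lapply(markers(), function(m) {
      pa <- pattern_prevalence(scored, m, group = ga)
      pb <- pattern_prevalence(scored, m, group = gb)
      # compare the top-scoring pattern of each marker, the convention
      # used for the published footnote comparisons
      top <- pattern_levels(m)[length(pattern_levels(m))]
      res <- compare_pattern_proportions(
        pa, pb, top,
        correct = config$continuity_correction
      )
      list(
        marker = m, target = top,
        table = unname(split(res$table, row(res$table))),
        chi_square = res$chi_square, df = res$df, p_value = res$p_value
      )
    })
    names(comparisons) <- markers()
  }

  summary <- list(
    schema_version = report_schema_version,
    config = list(
      cutoff = config$policy$cutoff,
      alert_threshold = config$policy$alert_threshold,
      min_coverage = config$min_coverage,
      continuity_correction = config$continuity_correction,
      seed = config$seed
    ),
    n_specimens = nrow(scored),
    groups = group_summaries,
    comparisons = comparisons
  )

  files <- character()
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    scored_path <- file.path(config$output_dir, "scored.csv")
    write_specimen_table(scored, scored_path)
    files <- scored_path
    if ("json" %in% config$format) {
      json_path <- file.path(config$output_dir, "report.json")
      jsonlite::write_json(summary, json_path,
        auto_unbox = TRUE, digits = NA, pretty = TRUE
      )
      files <- c(files, json_path)
    }
    if ("tsv" %in% config$format) {
      tsv_path <- file.path(config$output_dir, "report.tsv")
      flat <- do.call(rbind, lapply(names(group_summaries), function(g) {
        s <- group_summaries[[g]]
        data.frame(
          group = g, n = s$n,
          at_or_above_count = s$at_or_above$count,
          at_or_above_percent = s$at_or_above$percent
        )
      }))
      utils::write.table(flat, tsv_path,
        sep = "\t", row.names = FALSE, quote = FALSE
      )
      files <- c(files, tsv_path)
    }
  }

  invisible(list(scored = scored, summary = summary, files = files))
}
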