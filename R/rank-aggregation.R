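#' Convert raw pipeline scores to inclusive percentiles
#'
#' Applies [inclusive_percentile_rank()] within each (pipeline, context)
#' stratum of a combined score table.
#'
#' @param scores Score table with columns `pipeline_id`, `context_id`,
#'   `kinase_id`, `raw_score` (rows from the [adapters]).
#' @return `scores` with a `percentile` column in \[0, 100\].
#' @export
score_percentiles <- function(scores) {
  req <- c("pipeline_id", "context_id", "kinase_id", "raw_score")
  if (!all(req %in% names(scores))) {
    abort_bad_arg(sprintf("score table must have columns: %s", paste(req, collapse = ", ")))
  }
  if (anyDuplicated(scores[, c("pipeline_id", "context_id", "kinase_id")])) {
    abort_bad_arg("duplicate (pipeline, context, kinase) rows in score table")
  }
  scores |>
    dplyr::group_by(.data$pipeline_id, .data$context_id) |>
    dplyr::mutate(percentile = inclusive_percentile_rank(.data$raw_score)) |>
    dplyr::ungroup()
}

#' Unweighted average of reported percentiles
#'
#' Arithmetic mean over the pipelines that report the kinase; missing
#' pipelines are excluded from the denominator ("not reported" is never zero).
#'
#' @param percentiles Numeric vector, `NA` for non-reporting pipelines.
#' @return Mean of the non-missing values; errors if none report.
#' @export
unweighted_average <- function(percentiles) {
  reported <- percentiles[!is.na(percentiles)]
  if (length(reported) == 0L) {
    abort_bad_arg("at least one pipeline must report the kinase")
  }
  mean(reported)
}

#' Weighted average of reported percentiles
#'
#' Sum of the reported percentiles divided by the total number of pipelines
#' under consideration — equivalently the unweighted mean scaled by the
#' fraction of pipelines reporting, so kinases missed by some pipelines are
#' penalized and `weighted <= unweighted` always.
#'
#' @param percentiles Numeric vector, `NA` for non-reporting pipelines.
#' @param total_pipelines Total pipelines under consideration (>= number
#'   reporting).
#' @return Weighted average percentile.
#' @export
weighted_average <- function(percentiles, total_pipelines) {
  if (length(total_pipelines) != 1L || total_pipelines < 1) {
    abort_bad_arg("`total_pipelines` must be a positive count")
  }
  reported <- percentiles[!is.na(percentiles)]
  if (length(reported) == 0L) {
    abort_bad_arg("at least one pipeline must report the kinase")
  }
  if (length(reported) > total_pipelines) {
    abort_bad_arg("more reporting pipelines than `total_pipelines`")
  }
  sum(reported) / total_pipelines
}

#' Aggregate per-pipeline percentiles into consensus rankings
#'
#' For every (context, kinase) pair, collects the per-pipeline percentiles
#' into wide columns and computes the unweighted average (mean over reporting
#' pipelines) and the weighted average (sum over reporting pipelines divided
#' by `total_pipelines`). Full precision is retained; display rounding happens
#' in [top_k_table()].
#'
#' @param scores Percentile score table from [score_percentiles()].
#' @param total_pipelines Total pipelines under consideration; defaults to the
#'   number of distinct pipelines present in `scores`.
#' @param families Optional tibble `kinase_id`, `family_id` used to annotate
#'   rows.
#' @return Tibble with `context_id`, `kinase_id`, (`family_id`,) one
#'   percentile column per pipeline, `unweighted_avg`, `weighted_avg`.
#' @export
aggregate_rankings <- function(scores, total_pipelines = NULL, families = NULL) {
  if (!"percentile" %in% names(scores)) {
    abort_bad_arg("scores must carry a `percentile` column (see score_percentiles())")
  }
  pipelines <- sort(unique(scores$pipeline_id))
  if (is.null(total_pipelines)) {
    total_pipelines <- length(pipelines)
  }
  wide <- scores |>
    dplyr::select("context_id", "kinase_id", "pipeline_id", "percentile") |>
    tidyr::pivot_wider(names_from = "pipeline_id", values_from = "percentile") |>
    dplyr::select("context_id", "kinase_id", dplyr::all_of(pipelines))
  pcols <- as.matrix(wide[, pipelines, drop = FALSE])
  wide$unweighted_avg <- apply(pcols, 1, unweighted_average)
  wide$weighted_avg <- apply(pcols, 1, weighted_average, total_pipelines = total_pipelines)
  if (!is.null(families)) {
    wide <- dplyr::left_join(
      wide, dplyr::distinct(families, .data$kinase_id, .data$family_id),
      by = "kinase_id"
    ) |>
      dplyr::relocate("family_id", .after = "kinase_id")
  }
  dplyr::arrange(wide, .data$context_id, dplyr::desc(.data$unweighted_avg), .data$kinase_id)
}

#' Aggregate cell-line percentiles into group-level rankings
#'
#' For each pipeline and kinase, the group percentile is the mean of that
#' kinase's per-cell-line percentiles over the group members where it is
#' reported; the group rows are then combined exactly like single contexts. A
#' group of one cell line reproduces that cell line's ranking.
#'
#' @param scores Percentile score table from [score_percentiles()] covering
#'   the member cell lines.
#' @param groups Named list mapping group name to a character vector of member
#'   context ids, e.g. `list("Patient-Derived" = c("PDCL15", "PDCL5"))`.
#' @return Score table (same schema as `scores`) with one row set per group,
#'   `context_id` set to the group name; feed to [aggregate_rankings()].
#' @export
aggregate_groups <- function(scores, groups) {
  if (!is.list(groups) || is.null(names(groups)) || any(names(groups) == "")) {
    abort_bad_arg("`groups` must be a named list of member context vectors")
  }
  if (!"percentile" %in% names(scores)) {
    abort_bad_arg("scores must carry a `percentile` column")
  }
  purrr::imap_dfr(groups, function(members, group_name) {
    if (length(members) == 0L) {
      abort_bad_arg(sprintf("group '%s' is empty", group_name))
    }
    missing <- setdiff(members, unique(scores$context_id))
    if (length(missing) > 0L) {
      abort_bad_arg(sprintf(
        "group '%s': unknown context(s) %s", group_name, paste(missing, collapse = ", ")
      ))
    }
    scores |>
      dplyr::filter(.data$context_id %in% members) |>
      dplyr::group_by(.data$pipeline_id, .data$kinase_id) |>
      dplyr::summarise(
        raw_score = NA_real_,
        percentile = mean(.data$percentile),
        .groups = "drop"
      ) |>
      dplyr::mutate(context_id = group_name) |>
      dplyr::select("pipeline_id", "context_id", "kinase_id", "raw_score", "percentile")
  })
}

#' Top-k consensus ranking table
#'
#' Sorts an aggregated ranking descending by the chosen key, breaks ties
#' deterministically by kinase id (alphabetical), keeps the top `k` rows per
#' context, assigns sequential ranks, and rounds the displayed percentages to
#' integers (halves to even). Full-precision columns are kept alongside with a
#' `_exact` suffix.
#'
#' @param rankings Tibble from [aggregate_rankings()].
#' @param k Rows to keep per context (default 10).
#' @param sort_key `"unweighted_avg"` or `"weighted_avg"`.
#' @return Tibble with `context_id`, `rank`, `kinase_id`, (`family_id`,)
#'   rounded percentile columns and `_exact` companions.
#' @export
top_k_table <- function(rankings, k = 10L, sort_key = c("unweighted_avg", "weighted_avg")) {
  k <- check_count(k, "k", min = 1L)
  sort_key <- match.arg(sort_key)
  pipeline_cols <- setdiff(
    names(rankings),
    c("context_id", "kinase_id", "family_id", "unweighted_avg", "weighted_avg")
  )
  out <- rankings |>
    dplyr::group_by(.data$context_id) |>
    dplyr::arrange(dplyr::desc(.data[[sort_key]]), .data$kinase_id, .by_group = TRUE) |>
    dplyr::slice_head(n = k) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
  for (col in c(pipeline_cols, "unweighted_avg", "weighted_avg")) {
    out[[paste0(col, "_exact")]] <- out[[col]]
    out[[col]] <- round_percent(out[[col]])
  }
  dplyr::relocate(out, "context_id", "rank", "kinase_id")
}
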