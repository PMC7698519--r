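#' Load the published reference ranking tables
#'
#' The package ships the top-10 consensus kinase rankings published for three
#' pancreatic ductal adenocarcinoma comparisons (PANC1, PDCL15 and PDCL5 cell
#' lines versus wild-type pancreatic tissue, plus the Patient-Derived and All
#' groups) as golden fixtures: for each row, the per-pipeline inclusive
#' percentile columns and the printed consensus ("Average" or "Weighted
#' Average") value. They exercise the aggregation arithmetic — given the
#' printed per-pipeline percentiles, [aggregate_rankings()] must reproduce the
#' printed consensus within rounding of the inputs.
#'
#' @param which One of `"two_pipeline_average"`, `"two_pipeline_weighted"`
#'   (KRSA + UKA), `"four_pipeline_average"`, `"four_pipeline_weighted"`
#'   (KRSA, UKA, PTM-SEA, KEA3).
#' @return Tibble with columns `context_id`, `rank`, `kinase_id`, `family_id`,
#'   `printed` and one integer percentile column per pipeline (`NA` where the
#'   pipeline did not report the kinase).
#' @export
load_reference_rankings <- function(which = c("two_pipeline_average",
                                              "two_pipeline_weighted",
                                              "four_pipeline_average",
                                              "four_pipeline_weighted")) {
  which <- match.arg(which)
  path <- system.file(
    "extdata", sprintf("reference_rankings_%s.tsv", which),
    package = "kinomeRank", mustWork = TRUE
  )
  readr::read_tsv(path, col_types = readr::cols(
    context_id = readr::col_character(),
    rank = readr::col_integer(),
    kinase_id = readr::col_character(),
    family_id = readr::col_character(),
    .default = readr::col_double()
  ))
}

#' Recompute consensus averages from a reference ranking table
#'
#' Feeds the per-pipeline percentile columns of a reference table through
#' [unweighted_average()] / [weighted_average()] row by row and returns the
#' table with `recomputed` (rounded, halves to even) and `recomputed_exact`
#' columns next to `printed`.
#'
#' @param table Tibble from [load_reference_rankings()].
#' @param weighted Whether the printed column is a weighted average.
#' @param total_pipelines Total pipelines under consideration (2 or 4);
#'   defaults to the number of pipeline columns present.
#' @return The input with `recomputed_exact` and `recomputed` columns.
#' @export
recompute_reference_averages <- function(table, weighted = FALSE,
                                         total_pipelines = NULL) {
  pcols <- setdiff(names(table), c("context_id", "rank", "kinase_id", "family_id", "printed"))
  if (length(pcols) == 0L) {
    abort_bad_arg("table has no per-pipeline percentile columns")
  }
  if (is.null(total_pipelines)) {
    total_pipelines <- length(pcols)
  }
  mat <- as.matrix(table[, pcols, drop = FALSE])
  exact <- if (weighted) {
    apply(mat, 1, weighted_average, total_pipelines = total_pipelines)
  } else {
    apply(mat, 1, unweighted_average)
  }
  dplyr::mutate(table, recomputed_exact = exact, recomputed = round_percent(exact))
}
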