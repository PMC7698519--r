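#' Pipeline score adapters
#'
#' Each upstream-kinase pipeline reports a different statistic; the adapters
#' convert native output tables into a common score table with the orientation
#' "larger raw score = stronger evidence", ready for
#' [inclusive_percentile_rank()]. The common schema is `pipeline_id`,
#' `context_id`, `kinase_id`, `raw_score`.
#'
#' @name adapters
NULL

#' @describeIn adapters Upstream kinase analysis output: the raw score is the
#'   absolute value of the median final score, so strong decreases rank as
#'   high as strong increases.
#' @param data Native output table.
#' @param context_col,kinase_col Column names identifying the comparison and
#'   the kinase.
#' @param score_col Column holding the median final score.
#' @export
adapter_uka <- function(data, context_col = "context_id",
                        kinase_col = "kinase_id",
                        score_col = "median_final_score") {
  for (col in c(context_col, kinase_col, score_col)) {
    if (!col %in% names(data)) {
      abort_bad_arg(sprintf("column '%s' missing from UKA table", col))
    }
  }
  tibble::tibble(
    pipeline_id = "UKA",
    context_id = as.character(data[[context_col]]),
    kinase_id = as.character(data[[kinase_col]]),
    raw_score = abs(as.double(data[[score_col]]))
  )
}

#' @describeIn adapters Phosphosite signature enrichment output: rows not
#'   annotated as protein tyrosine kinases are dropped, and the raw score is
#'   the reciprocal of the FDR-scaled geometric-mean-LFC statistic
#'   (`fdr.pvalue.totalGeoMeanLFC`), so smaller FDR values rank higher. A zero
#'   statistic yields an `Inf` sentinel that ranks top, with a warning.
#' @param value_col Column holding `fdr.pvalue.totalGeoMeanLFC`.
#' @param type_col Column with the kinase class; rows are kept when it equals
#'   `"TK"` (tyrosine kinase).
#' @export
adapter_ptmsea <- function(data, context_col = "context_id",
                           kinase_col = "kinase_id",
                           value_col = "fdr_pvalue_totalGeoMeanLFC",
                           type_col = "kinase_type") {
  for (col in c(context_col, kinase_col, value_col, type_col)) {
    if (!col %in% names(data)) {
      abort_bad_arg(sprintf("column '%s' missing from PTM-SEA table", col))
    }
  }
  data <- data[data[[type_col]] == "TK", , drop = FALSE]
  val <- as.double(data[[value_col]])
  if (any(val == 0, na.rm = TRUE)) {
    warning("zero fdr.pvalue.totalGeoMeanLFC; using +Inf sentinel (ranks top)",
            call. = FALSE)
  }
  tibble::tibble(
    pipeline_id = "PTMSEA",
    context_id = as.character(data[[context_col]]),
    kinase_id = as.character(data[[kinase_col]]),
    raw_score = 1 / val
  )
}

#' @describeIn adapters Kinase enrichment analysis output: FDR p-values from
#'   the 0.2, 0.3 and 0.4 LFC-cutoff input lists are averaged within each
#'   substrate database (ChengKSIN, PTMsigDB, PhosDAll), the three database
#'   means are averaged, and the raw score is `-log10` of the grand mean. A
#'   kinase absent from one database contributes only the databases that
#'   report it, with a warning.
#' @param fdr_col Column holding the FDR p-value.
#' @param database_col,cutoff_col Columns identifying the substrate database
#'   and the LFC cutoff of the input list.
#' @export
adapter_kea3 <- function(data, context_col = "context_id",
                         kinase_col = "kinase_id",
                         database_col = "database",
                         cutoff_col = "lfc_cutoff",
                         fdr_col = "fdr") {
  for (col in c(context_col, kinase_col, database_col, cutoff_col, fdr_col)) {
    if (!col %in% names(data)) {
      abort_bad_arg(sprintf("column '%s' missing from KEA3 table", col))
    }
  }
  databases <- c("ChengKSIN", "PTMsigDB", "PhosDAll")
  bad <- setdiff(unique(data[[database_col]]), databases)
  if (length(bad) > 0L) {
    abort_bad_arg(sprintf("unknown KEA3 database(s): %s", paste(bad, collapse = ", ")))
  }
  df <- tibble::tibble(
    context_id = as.character(data[[context_col]]),
    kinase_id = as.character(data[[kinase_col]]),
    database = as.character(data[[database_col]]),
    cutoff = as.double(data[[cutoff_col]]),
    fdr = as.double(data[[fdr_col]])
  )
  per_db <- df |>
    dplyr::group_by(.data$context_id, .data$kinase_id, .data$database) |>
    dplyr::summarise(db_mean = mean(.data$fdr), .groups = "drop")
  incomplete <- per_db |>
    dplyr::count(.data$context_id, .data$kinase_id) |>
    dplyr::filter(.data$n < length(databases))
  if (nrow(incomplete) > 0L) {
    warning(sprintf(
      "%d kinase(s) missing from one or more KEA3 databases; averaging over reporting databases only",
      nrow(incomplete)
    ), call. = FALSE)
  }
  per_db |>
    dplyr::group_by(.data$context_id, .data$kinase_id) |>
    dplyr::summarise(grand = mean(.data$db_mean), .groups = "drop") |>
    dplyr::transmute(
      pipeline_id = "KEA3",
      context_id = .data$context_id,
      kinase_id = .data$kinase_id,
      raw_score = -log10(.data$grand)
    )
}

#' @describeIn adapters Random-sampling analysis results: family percentiles
#'   are broadcast to member kinases and re-expressed as a score table. The
#'   raw score is the absolute mean log2 fold change; the percentile computed
#'   from it equals the family percentile from [krsa_percentiles()].
#' @param results Family results from [krsa()] / [krsa_percentiles()].
#' @param families Tibble `kinase_id`, `family_id`.
#' @param context_id Identifier of the comparison (cell line).
#' @export
adapter_krsa <- function(results, families, context_id) {
  scored <- dplyr::filter(results, !is.na(.data$mean_log2fc))
  broadcast_family_scores(
    dplyr::select(scored, "family_id", "mean_log2fc"),
    families
  ) |>
    dplyr::transmute(
      pipeline_id = "KRSA",
      context_id = as.character(context_id),
      kinase_id = .data$kinase_id,
      raw_score = abs(.data$mean_log2fc)
    )
}
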