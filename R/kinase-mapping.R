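#' Apply database-specific selection rules to kinase-substrate records
#'
#' Filters raw kinase-peptide association records the way predictions from
#' heterogeneous phosphorylation-site databases are curated before mapping:
#' \describe{
#'   \item{GPS}{kept only when `score > 2 * prediction_threshold` (strict);
#'     records missing the threshold are rejected with a warning.}
#'   \item{Kinexus}{kept only when `rank <= 5` within each peptide; ties at
#'     rank 5 are all kept.}
#'   \item{PhosphoELM / PhosphoSitePlus / synthetic}{kept unconditionally
#'     (curated experimental evidence).}
#' }
#' The operation is idempotent: re-applying it to its own output changes
#' nothing.
#'
#' @param records Tibble with columns `source`, `kinase_id`, `peptide_id` and
#'   optionally `score`, `prediction_threshold`, `rank`.
#' @return The retained records.
#' @export
select_records <- function(records) {
  req <- c("source", "kinase_id", "peptide_id")
  if (!all(req %in% names(records))) {
    abort_bad_arg(sprintf("records must have columns: %s", paste(req, collapse = ", ")))
  }
  known <- c("GPS", "Kinexus", "PhosphoELM", "PhosphoSitePlus", "synthetic")
  bad <- setdiff(unique(records$source), known)
  if (length(bad) > 0L) {
    abort_bad_arg(sprintf("unknown record source(s): %s", paste(bad, collapse = ", ")))
  }
  for (col in c("score", "prediction_threshold", "rank")) {
    if (!col %in% names(records)) records[[col]] <- NA_real_
  }

  gps <- dplyr::filter(records, .data$source == "GPS")
  gps_missing <- is.na(gps$score) | is.na(gps$prediction_threshold)
  if (any(gps_missing)) {
    warning(sprintf("dropping %d GPS record(s) without score or prediction threshold",
                    sum(gps_missing)), call. = FALSE)
    gps <- gps[!gps_missing, ]
  }
  gps <- dplyr::filter(gps, .data$score > 2 * .data$prediction_threshold)

  kinexus <- records |>
    dplyr::filter(.data$source == "Kinexus") |>
    dplyr::filter(!is.na(.data$rank) & .data$rank <= 5)

  unconditional <- dplyr::filter(
    records,
    .data$source %in% c("PhosphoELM", "PhosphoSitePlus", "synthetic")
  )

  dplyr::bind_rows(gps, kinexus, unconditional)
}

#' Build a deduplicated kinase-peptide map with family assignments
#'
#' Unions selected records across databases into one association table: each
#' (kinase, peptide) pair appears once, with its supporting sources joined by
#' semicolons, and every kinase annotated with its family from the supplied
#' assignment table.
#'
#' @param selected Records from [select_records()].
#' @param families Tibble with columns `kinase_id`, `family_id`; every kinase
#'   in `selected` must appear exactly once.
#' @return Tibble `kinase_id`, `family_id`, `peptide_id`, `sources`.
#' @export
build_map <- function(selected, families) {
  stopifnot(is.data.frame(selected), is.data.frame(families))
  if (nrow(selected) == 0L) {
    return(tibble::tibble(
      kinase_id = character(), family_id = character(),
      peptide_id = character(), sources = character()
    ))
  }
  orphans <- setdiff(unique(selected$kinase_id), families$kinase_id)
  if (length(orphans) > 0L) {
    abort_bad_arg(sprintf(
      "kinase(s) without family assignment: %s", paste(sort(orphans), collapse = ", ")
    ))
  }
  if (anyDuplicated(families$kinase_id)) {
    abort_bad_arg("`families` must assign each kinase exactly one family")
  }
  selected |>
    dplyr::group_by(.data$kinase_id, .data$peptide_id) |>
    dplyr::summarise(
      sources = paste(sort(unique(.data$source)), collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      dplyr::select(families, "kinase_id", "family_id"),
      by = "kinase_id"
    ) |>
    dplyr::select("kinase_id", "family_id", "peptide_id", "sources") |>
    dplyr::arrange(.data$kinase_id, .data$peptide_id)
}

#' Collapse a kinase-peptide map to kinase families
#'
#' Family-level scoring assigns identical scores to all members of a kinase
#' family, so the family's substrate set is the union of its members' peptide
#' sets. Total peptide coverage is preserved: the union over families equals
#' the union over kinases.
#'
#' @param map Tibble with columns `family_id`, `peptide_id` (e.g. from
#'   [build_map()] or [generate_map()]).
#' @return Tibble `family_id`, `peptide_id`, one row per distinct pair.
#' @export
collapse_to_families <- function(map) {
  stopifnot(all(c("family_id", "peptide_id") %in% names(map)))
  map |>
    dplyr::distinct(.data$family_id, .data$peptide_id) |>
    dplyr::arrange(.data$family_id, .data$peptide_id)
}

#' Broadcast family-level scores to member kinases
#'
#' Given per-family scores and the kinase-family assignment, returns a
#' kinase-level table in which every member of a family carries that family's
#' values unchanged.
#'
#' @param family_scores Tibble keyed by `family_id`.
#' @param families Tibble `kinase_id`, `family_id`.
#' @return `family_scores` expanded to one row per member kinase.
#' @export
broadcast_family_scores <- function(family_scores, families) {
  stopifnot(
    "family_id" %in% names(family_scores),
    all(c("kinase_id", "family_id") %in% names(families))
  )
  dplyr::inner_join(
    dplyr::distinct(families, .data$kinase_id, .data$family_id),
    family_scores,
    by = "family_id"
  )
}

#' Read and write kinase-peptide map TSVs
#'
#' The on-disk schema is `kinase_id`, `family_id`, `peptide_id`, `sources`
#' (semicolon-joined); a written map reads back identically.
#'
#' @param map Map tibble.
#' @param path TSV path.
#' @return `read_map_tsv()` returns the map tibble; `write_map_tsv()` its path,
#'   invisibly.
#' @export
write_map_tsv <- function(map, path) {
  readr::write_tsv(map, path)
  invisible(path)
}

#' @rdname write_map_tsv
#' @export
read_map_tsv <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      kinase_id = readr::col_character(),
      family_id = readr::col_character(),
      peptide_id = readr::col_character(),
      sources = readr::col_character()
    )
  )
}
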