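#' Pipeline configuration
#'
#' Assembles and validates the settings for an end-to-end run: the synthetic
#' chip (peptides, controls, kinases), the per-context spiked truths, the
#' signal-processing thresholds, the resampling settings, and the aggregation
#' layout. Validation is strict and happens before any computation: the fold
#' change thresholds must satisfy `fc_up > 1 > fc_down > 0` and the R-squared
#' minimum must lie in (0, 1].
#'
#' @param contexts Named list: context id (cell line) to a list with element
#'   `spiked` (tibble `kinase_id`, `effect_log2fc`, possibly empty).
#' @param groups Named list of context groups for group-level rankings.
#' @param seed Global integer seed; all stage substreams derive from it.
#' @param n_peptides,n_controls,n_kinases,mean_peptides Chip and map geometry.
#' @param noise_sd,nonlinear_fraction,undetectable_fraction Generator noise
#'   settings (see [synthetic_truth()]).
#' @param r2_min,fc_up,fc_down Signal-processing thresholds.
#' @param iterations,z_threshold,include_controls Resampling settings (see
#'   [krsa_config()]).
#' @param total_pipelines Total pipelines for weighted averaging (4 when the
#'   external score tables are simulated, else 1).
#' @param simulate_adapters Whether to simulate the three external pipelines'
#'   score tables ([simulate_pipeline_scores()]).
#' @param top_k Rows per context in the report tables.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(contexts, groups = list(), seed = 1L,
                            n_peptides = 196L, n_controls = 3L,
                            n_kinases = 60L, mean_peptides = 8,
                            noise_sd = 20, nonlinear_fraction = 0,
                            undetectable_fraction = 0,
                            r2_min = 0.90, fc_up = 1.30, fc_down = 0.70,
                            iterations = 3000L, z_threshold = 2,
                            include_controls = TRUE,
                            total_pipelines = NULL,
                            simulate_adapters = TRUE,
                            top_k = 10L) {
  if (!is.list(contexts) || length(contexts) == 0L || is.null(names(contexts))) {
    abort_bad_arg("`contexts` must be a non-empty named list")
  }
  if (!(fc_up > 1 && 1 > fc_down && fc_down > 0)) {
    abort_bad_arg("thresholds must satisfy fc_up > 1 > fc_down > 0")
  }
  if (r2_min <= 0 || r2_min > 1) {
    abort_bad_arg("`r2_min` must lie in (0, 1]")
  }
  if (is.null(total_pipelines)) {
    total_pipelines <- if (simulate_adapters) 4L else 1L
  }
  structure(
    list(
      contexts = contexts, groups = groups, seed = as.integer(seed),
      n_peptides = n_peptides, n_controls = n_controls,
      n_kinases = n_kinases, mean_peptides = mean_peptides,
      noise_sd = noise_sd, nonlinear_fraction = nonlinear_fraction,
      undetectable_fraction = undetectable_fraction,
      r2_min = r2_min, fc_up = fc_up, fc_down = fc_down,
      iterations = iterations, z_threshold = z_threshold,
      include_controls = include_controls,
      total_pipelines = total_pipelines,
      simulate_adapters = isTRUE(simulate_adapters),
      top_k = top_k
    ),
    class = "pipeline_config"
  )
}

#' Run the end-to-end analysis
#'
#' Executes simulate -> slope fitting -> filtering -> fold change ->
#' resampling analysis -> (optional simulated external pipelines) ->
#' percentile conversion -> per-context and group aggregation -> top-k report
#' tables. Identical config and seed give byte-identical outputs; when
#' `out_dir` is given, the ranking tables are written as TSV together with a
#' YAML manifest recording the seed, stage counts and MD5 digests of every
#' file written.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return List with `scores` (long percentile table), `rankings`
#'   (aggregated, contexts and groups), `top_unweighted` / `top_weighted`
#'   (report tables), `details` (per-context stage outputs), and `manifest`
#'   (also written as YAML when `out_dir` is given).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  catalog <- generate_catalog(config$n_peptides, config$n_controls,
                              seed = derive_seed(config$seed, 1L))
  map <- generate_map(catalog, config$n_kinases, config$mean_peptides,
                      seed = derive_seed(config$seed, 2L))
  families <- dplyr::distinct(map, .data$kinase_id, .data$family_id)
  fam_map <- collapse_to_families(map)
  universe <- if (config$include_controls) {
    catalog$peptide_id
  } else {
    catalog$peptide_id[!catalog$is_internal_control]
  }

  details <- list()
  all_scores <- list()
  for (i in seq_along(config$contexts)) {
    ctx <- names(config$contexts)[i]
    spec <- config$contexts[[i]]
    ctx_seed <- derive_seed(config$seed, 100L + i)
    truth <- synthetic_truth(
      spiked_kinases = spec$spiked,
      noise_sd = config$noise_sd,
      nonlinear_fraction = config$nonlinear_fraction,
      undetectable_fraction = config$undetectable_fraction,
      seed = ctx_seed
    )
    run <- simulate_run(catalog, map, truth)
    fits <- fit_run_slopes(run$intensities)
    retained <- filter_peptides(fits, r2_min = config$r2_min, catalog = catalog)
    pfc <- compute_fold_change(fits, retained,
                               fc_up = config$fc_up, fc_down = config$fc_down)
    kcfg <- krsa_config(config$iterations, seed = ctx_seed,
                        z_threshold = config$z_threshold,
                        include_controls = config$include_controls)
    kres <- krsa(pfc, fam_map, universe, kcfg)
    scores <- list(adapter_krsa(kres, families, ctx))
    if (config$simulate_adapters) {
      native <- simulate_pipeline_scores(map, truth, ctx, seed = ctx_seed)
      scores <- c(scores, list(
        adapter_uka(native$uka),
        adapter_ptmsea(native$ptmsea),
        adapter_kea3(native$kea3)
      ))
    }
    details[[ctx]] <- list(
      truth = truth, n_retained = length(retained),
      n_differential = sum(pfc$is_differential), krsa = kres
    )
    all_scores[[ctx]] <- dplyr::bind_rows(scores)
  }

  scores <- score_percentiles(dplyr::bind_rows(all_scores))
  if (length(config$groups) > 0L) {
    scores <- dplyr::bind_rows(scores, aggregate_groups(scores, config$groups))
  }
  rankings <- aggregate_rankings(scores, total_pipelines = config$total_pipelines,
                                 families = families)
  top_unweighted <- top_k_table(rankings, k = config$top_k, sort_key = "unweighted_avg")
  top_weighted <- top_k_table(rankings, k = config$top_k, sort_key = "weighted_avg")

  manifest <- list(
    seed = config$seed,
    contexts = lapply(details, function(d) list(
      seed = d$truth$seed,
      spiked = as.list(d$truth$spiked_kinases),
      peptides_retained = d$n_retained,
      differential_peptides = d$n_differential
    )),
    total_pipelines = config$total_pipelines,
    families_scored = length(unique(fam_map$family_id))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      rankings = file.path(out_dir, "rankings.tsv"),
      top_unweighted = file.path(out_dir, "top_unweighted.tsv"),
      top_weighted = file.path(out_dir, "top_weighted.tsv")
    )
    readr::write_tsv(rankings, paths[["rankings"]])
    readr::write_tsv(top_unweighted, paths[["top_unweighted"]])
    readr::write_tsv(top_weighted, paths[["top_weighted"]])
    manifest$files <- as.list(tools::md5sum(unname(paths)))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }

  list(
    scores = scores, rankings = rankings,
    top_unweighted = top_unweighted, top_weighted = top_weighted,
    details = details, manifest = manifest,
    catalog = catalog, map = map
  )
}

#' Validate a tabular input file against a known schema
#'
#' Checks a TSV against one of the pipeline's table schemas and returns a
#' diagnostics tibble (zero rows when the file is well formed). Never mutates
#' the input.
#'
#' Schemas: `"run"` (long intensity table: non-negative exposures, finite
#' intensities, positive replicate indices), `"map"` (kinase-peptide map: one
#' family per kinase), `"scores"` (pipeline score table: finite raw scores).
#'
#' @param path Path to a TSV file.
#' @param schema_id One of `"run"`, `"map"`, `"scores"`.
#' @return Tibble with columns `row`, `column`, `message`.
#' @export
validate_table <- function(path, schema_id = c("run", "map", "scores")) {
  schema_id <- match.arg(schema_id)
  if (!file.exists(path)) {
    abort_bad_arg(sprintf("file not found: %s", path))
  }
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  diag <- function(row, column, message) {
    tibble::tibble(row = as.integer(row), column = column, message = message)
  }
  out <- list()
  required <- switch(schema_id,
    run = c("sample_id", "condition", "replicate", "peptide_id", "exposure_ms", "intensity"),
    map = c("kinase_id", "family_id", "peptide_id"),
    scores = c("pipeline_id", "context_id", "kinase_id", "raw_score")
  )
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L) {
    return(diag(NA_integer_, miss, "required column missing"))
  }
  if (schema_id == "run") {
    bad <- which(!is.finite(df$exposure_ms) | df$exposure_ms < 0)
    if (length(bad)) out <- c(out, list(diag(bad, "exposure_ms", "negative or non-finite exposure")))
    bad <- which(!is.finite(df$intensity))
    if (length(bad)) out <- c(out, list(diag(bad, "intensity", "non-finite intensity")))
    bad <- which(is.na(df$replicate) | df$replicate < 1)
    if (length(bad)) out <- c(out, list(diag(bad, "replicate", "replicate index must be >= 1")))
  } else if (schema_id == "map") {
    fam_per_kin <- tapply(df$family_id, df$kinase_id, function(x) length(unique(x)))
    multi <- names(fam_per_kin)[fam_per_kin > 1]
    if (length(multi)) {
      rows <- which(df$kinase_id %in% multi)
      out <- c(out, list(diag(rows, "family_id", "kinase assigned to multiple families")))
    }
    bad <- which(is.na(df$peptide_id) | df$peptide_id == "")
    if (length(bad)) out <- c(out, list(diag(bad, "peptide_id", "empty peptide id")))
  } else {
    bad <- which(is.na(df$raw_score) | is.nan(df$raw_score))
    if (length(bad)) out <- c(out, list(diag(bad, "raw_score", "missing raw score")))
  }
  if (length(out) == 0L) {
    return(diag(integer(), character(), character()))
  }
  dplyr::bind_rows(out)
}
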