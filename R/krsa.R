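#' KRSA configuration
#'
#' Settings for the kinome random-sampling analysis: number of resampling
#' iterations (default 3000), the peptide universe to draw from (by default
#' all chip peptides including internal controls; set
#' `include_controls = FALSE` to draw from the 193 non-control peptides), the
#' seed, and the |Z| significance threshold (default 2).
#'
#' @param iterations Resampling iterations (>= 1, default 3000).
#' @param seed Integer seed.
#' @param z_threshold Significance threshold on |Z| (default 2).
#' @param include_controls Whether internal controls stay in the sampling
#'   universe (default TRUE).
#' @return A list of class `krsa_config`.
#' @export
krsa_config <- function(iterations = 3000L, seed = 1L, z_threshold = 2,
                        include_controls = TRUE) {
  iterations <- check_count(iterations, "iterations", min = 1L)
  structure(
    list(
      iterations = iterations,
      seed = as.integer(seed),
      z_threshold = z_threshold,
      include_controls = isTRUE(include_controls)
    ),
    class = "krsa_config"
  )
}

#' Observed per-family hit counts among differential peptides
#'
#' The hit count of family F is the size of the intersection between the
#' differential peptide set and F's mapped peptide set. Families mapped to no
#' differential peptide count 0.
#'
#' @param differential_peptides Character vector of differential peptide ids.
#' @param family_map Tibble `family_id`, `peptide_id` (see
#'   [collapse_to_families()]).
#' @return Tibble `family_id`, `observed_hits` covering every family in the
#'   map.
#' @export
observed_hits <- function(differential_peptides, family_map) {
  stopifnot(all(c("family_id", "peptide_id") %in% names(family_map)))
  family_map |>
    dplyr::distinct(.data$family_id, .data$peptide_id) |>
    dplyr::group_by(.data$family_id) |>
    dplyr::summarise(
      observed_hits = sum(.data$peptide_id %in% differential_peptides),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$family_id)
}

#' Empirical resampling null for per-family hit counts
#'
#' Each iteration draws `m` peptides uniformly without replacement from the
#' peptide universe and records the per-family hit counts; the null mean and
#' SD are the empirical moments over iterations. As iterations grow these
#' converge to the closed-form hypergeometric moments: mean `m * k / N` and SD
#' `sqrt(m * (k/N) * (1 - k/N) * (N - m) / (N - 1))` for a family with `k`
#' mapped universe peptides.
#'
#' @param m Number of differential peptides to draw per iteration
#'   (`0 <= m <= length(universe)`).
#' @param family_map Tibble `family_id`, `peptide_id`.
#' @param universe Character vector of all chip peptide ids to sample from.
#' @param config A [krsa_config()]; its seed makes the null reproducible.
#' @return Tibble `family_id`, `null_mean`, `null_sd`.
#' @export
resample_null <- function(m, family_map, universe, config = krsa_config()) {
  stopifnot(inherits(config, "krsa_config"))
  n_univ <- length(universe)
  if (n_univ < 1L) abort_bad_arg("`universe` must not be empty")
  if (m < 0 || m > n_univ) {
    abort_bad_arg(sprintf("`m` must be between 0 and the universe size (%d)", n_univ))
  }
  m <- as.integer(m)
  fams <- sort(unique(family_map$family_id))
  # membership matrix: universe peptides x families
  memb <- vapply(fams, function(f) {
    universe %in% family_map$peptide_id[family_map$family_id == f]
  }, logical(n_univ))
  memb <- matrix(as.numeric(memb), nrow = n_univ,
                 dimnames = list(NULL, fams))

  B <- config$iterations
  if (m == 0L) {
    counts <- matrix(0, nrow = length(fams), ncol = B, dimnames = list(fams, NULL))
  } else {
    set.seed(derive_seed(config$seed, 23L))
    draws <- replicate(B, sample.int(n_univ, m))       # m x B
    ind <- matrix(0, nrow = n_univ, ncol = B)
    ind[cbind(as.vector(draws), rep(seq_len(B), each = m))] <- 1
    counts <- crossprod(memb, ind)                     # families x B
  }
  tibble::tibble(
    family_id = fams,
    null_mean = unname(rowMeans(counts)),
    null_sd = unname(apply(counts, 1, sd))
  )
}

#' Score kinase families against the resampling null
#'
#' Combines observed hit counts with the null moments into Z-scores
#' `(observed - null_mean) / null_sd` and annotates each family with the mean
#' log2 fold change of its differential peptides (the directionality readout:
#' increased activity when positive, decreased when negative).
#'
#' Degenerate families with `null_sd = 0` receive Z = 0 when the observed
#' count equals the null mean and are flagged `degenerate` (Z = NA) otherwise.
#' Families with no differential peptides have `mean_log2fc = NA` and no
#' direction.
#'
#' @param observed Tibble from [observed_hits()].
#' @param null Tibble from [resample_null()]; must cover the same families.
#' @param diff_log2fc Tibble `peptide_id`, `log2fc` restricted to the
#'   differential peptides.
#' @param family_map Tibble `family_id`, `peptide_id`.
#' @param config A [krsa_config()] (supplies the |Z| threshold annotation).
#' @return Tibble `family_id`, `observed_hits`, `null_mean`, `null_sd`,
#'   `z_score`, `degenerate`, `mean_log2fc`, `direction`, `significant`.
#' @export
score_families <- function(observed, null, diff_log2fc, family_map,
                           config = krsa_config()) {
  missing_null <- setdiff(observed$family_id, null$family_id)
  if (length(missing_null) > 0L) {
    abort_bad_arg(sprintf(
      "families absent from null: %s", paste(missing_null, collapse = ", ")
    ))
  }
  fam_lfc <- family_map |>
    dplyr::distinct(.data$family_id, .data$peptide_id) |>
    dplyr::inner_join(diff_log2fc, by = "peptide_id") |>
    dplyr::group_by(.data$family_id) |>
    dplyr::summarise(mean_log2fc = mean(.data$log2fc), .groups = "drop")

  observed |>
    dplyr::inner_join(null, by = "family_id") |>
    dplyr::left_join(fam_lfc, by = "family_id") |>
    dplyr::mutate(
      degenerate = .data$null_sd == 0 & .data$observed_hits != .data$null_mean,
      z_score = dplyr::case_when(
        .data$null_sd > 0 ~ (.data$observed_hits - .data$null_mean) / .data$null_sd,
        .data$observed_hits == .data$null_mean ~ 0,
        TRUE ~ NA_real_
      ),
      direction = dplyr::if_else(
        is.na(.data$mean_log2fc), NA_character_,
        dplyr::if_else(.data$mean_log2fc > 0, "increased", "decreased")
      ),
      significant = !is.na(.data$z_score) & abs(.data$z_score) >= config$z_threshold
    ) |>
    dplyr::arrange(.data$family_id)
}

#' Attach inclusive percentile ranks to KRSA family scores
#'
#' Family percentiles are computed from the absolute value of the mean log2
#' fold change via [inclusive_percentile_rank()]; families with no
#' differential peptides (NA mean) are left unranked. Use
#' [broadcast_family_scores()] to copy the family percentile onto member
#' kinases.
#'
#' @param results Tibble from [score_families()].
#' @return `results` with a `percentile` column.
#' @export
krsa_percentiles <- function(results) {
  if (nrow(results) == 0L) abort_bad_arg("need at least one family")
  ranked <- !is.na(results$mean_log2fc)
  pct <- rep(NA_real_, nrow(results))
  if (any(ranked)) {
    pct[ranked] <- inclusive_percentile_rank(abs(results$mean_log2fc[ranked]))
  }
  dplyr::mutate(results, percentile = pct)
}

#' Run the full kinome random-sampling analysis
#'
#' Convenience wrapper: counts observed per-family hits among the differential
#' peptides, builds the resampling null (drawing `m =` number of differential
#' peptides per iteration), scores families, and attaches percentiles.
#'
#' @param peptide_fc Fold-change table from [compute_fold_change()].
#' @param family_map Tibble `family_id`, `peptide_id`.
#' @param universe Character vector of chip peptide ids (the sampling
#'   universe, typically all 196 spots).
#' @param config A [krsa_config()].
#' @return Tibble as from [krsa_percentiles()].
#' @export
krsa <- function(peptide_fc, family_map, universe, config = krsa_config()) {
  diff <- dplyr::filter(peptide_fc, .data$is_differential)
  extra <- setdiff(diff$peptide_id, universe)
  if (length(extra) > 0L) {
    abort_bad_arg("differential peptides must be contained in the universe")
  }
  obs <- observed_hits(diff$peptide_id, family_map)
  null <- resample_null(nrow(diff), family_map, universe, config)
  score_families(
    obs, null,
    dplyr::select(diff, "peptide_id", "log2fc"),
    family_map, config
  ) |>
    krsa_percentiles()
}
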