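#' Generate a peptide catalog for a synthetic tyrosine-kinase chip
#'
#' Builds the spot catalog of a synthetic array emulating a tyrosine-kinase
#' peptide chip: by default 196 reporter peptides of which 3 are internal
#' controls. Internal controls carry condition-independent signal and are never
#' mapped to kinases.
#'
#' @param n_peptides Total number of peptide spots (default 196).
#' @param n_controls Number of internal-control spots (default 3); must be
#'   smaller than `n_peptides`.
#' @param seed Integer seed; identical seeds give identical catalogs.
#' @return A tibble with columns `peptide_id`, `substrate_label`,
#'   `is_internal_control`.
#' @examples
#' cat196 <- generate_catalog()
#' sum(cat196$is_internal_control) # 3
#' @export
generate_catalog <- function(n_peptides = 196L, n_controls = 3L, seed = 1L) {
  n_peptides <- check_count(n_peptides, "n_peptides", min = 1L)
  n_controls <- check_count(n_controls, "n_controls", min = 0L)
  if (n_controls >= n_peptides) {
    abort_bad_arg("`n_controls` must be smaller than `n_peptides`")
  }
  set.seed(derive_seed(seed, 11L))
  ids <- sprintf("pep_%03d", seq_len(n_peptides))
  # synthetic consensus phosphosite labels: GENE_start_end style
  genes <- replicate(n_peptides, paste0(
    paste(sample(LETTERS, 3L, replace = TRUE), collapse = ""),
    sample(1:9, 1L)
  ))
  start <- sample(1:900, n_peptides, replace = TRUE)
  labels <- sprintf("%s_%d_%d", genes, start, start + 12L)
  controls <- rep(FALSE, n_peptides)
  if (n_controls > 0L) {
    controls[sample.int(n_peptides, n_controls)] <- TRUE
  }
  tibble::tibble(
    peptide_id = ids,
    substrate_label = labels,
    is_internal_control = controls
  )
}

#' Generate a synthetic kinase-peptide map
#'
#' Emulates the bipartite kinase-substrate association table obtained from
#' phosphorylation-site databases: each kinase is assigned to a family and to a
#' random set of non-control peptides. Families partition the kinases so that
#' family-level peptide sets are unions over members, as in family-level
#' upstream-kinase scoring.
#'
#' @param catalog Peptide catalog from [generate_catalog()].
#' @param n_kinases Number of kinases (>= 1).
#' @param mean_peptides Mean peptides per kinase (Poisson-distributed, >= 1).
#' @param n_families Number of families; defaults to roughly `n_kinases / 2.5`
#'   so that typical families have 2-3 members.
#' @param seed Integer seed.
#' @return A tibble with columns `kinase_id`, `family_id`, `peptide_id`,
#'   `sources` (here always `"synthetic"`); one row per association,
#'   deduplicated.
#' @export
generate_map <- function(catalog, n_kinases = 60L, mean_peptides = 8,
                         n_families = NULL, seed = 1L) {
  n_kinases <- check_count(n_kinases, "n_kinases", min = 1L)
  stopifnot(is.data.frame(catalog))
  pool <- catalog$peptide_id[!catalog$is_internal_control]
  if (length(pool) == 0L) {
    abort_bad_arg("catalog has no non-control peptides to map")
  }
  if (is.null(n_families)) {
    n_families <- max(1L, as.integer(ceiling(n_kinases / 2.5)))
  }
  n_families <- check_count(n_families, "n_families", min = 1L)
  set.seed(derive_seed(seed, 13L))
  kinases <- sprintf("KIN%02d", seq_len(n_kinases))
  fam_ids <- sprintf("FAM%02d", seq_len(n_families))
  # every family gets at least one member, remainder assigned at random
  fam_of <- c(fam_ids[seq_len(min(n_families, n_kinases))],
              sample(fam_ids, max(0L, n_kinases - n_families), replace = TRUE))
  fam_of <- fam_of[seq_len(n_kinases)]
  sizes <- pmin(length(pool), rpois(n_kinases, lambda = max(0, mean_peptides - 1)) + 1L)
  entries <- purrr::map2_dfr(kinases, seq_len(n_kinases), function(k, i) {
    tibble::tibble(
      kinase_id = k,
      family_id = fam_of[i],
      peptide_id = sample(pool, sizes[i])
    )
  })
  entries$sources <- "synthetic"
  dplyr::distinct(entries, .data$kinase_id, .data$peptide_id, .keep_all = TRUE)
}

#' Describe the ground truth of a synthetic comparison
#'
#' Bundles the parameters controlling one synthetic case-versus-control
#' comparison: which kinases are spiked (differentially active) and by how
#' much, the additive Gaussian intensity noise, the range of baseline exposure
#' slopes, and the fractions of peptides designated nonlinear (saturating
#' signal) or undetectable (non-positive slope).
#'
#' Defaults reflect a triplicate tyrosine-kinase chip run: baseline slopes of
#' 1-3 intensity units per millisecond (peak intensities of a few hundred
#' units at the 200 ms exposure) and noise_sd = 20 intensity units, i.e.
#' moderate noise relative to signal.
#'
#' @param spiked_kinases Tibble with columns `kinase_id`, `effect_log2fc`, or
#'   `NULL` for a null comparison.
#' @param noise_sd Additive Gaussian intensity noise SD (fluorescence units,
#'   >= 0), homoscedastic across exposures.
#' @param baseline_slope_range Length-2 numeric, uniform range of baseline
#'   slopes (intensity units per ms).
#' @param nonlinear_fraction,undetectable_fraction Fractions of catalog
#'   peptides designated nonlinear / undetectable; must sum to < 1.
#' @param seed Integer seed for the simulation substreams.
#' @return A list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(spiked_kinases = NULL, noise_sd = 20,
                            baseline_slope_range = c(1, 3),
                            nonlinear_fraction = 0,
                            undetectable_fraction = 0,
                            seed = 1L) {
  if (is.null(spiked_kinases)) {
    spiked_kinases <- tibble::tibble(kinase_id = character(), effect_log2fc = double())
  }
  stopifnot(
    is.data.frame(spiked_kinases),
    all(c("kinase_id", "effect_log2fc") %in% names(spiked_kinases)),
    length(noise_sd) == 1L, noise_sd >= 0,
    length(baseline_slope_range) == 2L,
    baseline_slope_range[1] > 0,
    diff(baseline_slope_range) >= 0
  )
  if (nonlinear_fraction < 0 || undetectable_fraction < 0 ||
      nonlinear_fraction + undetectable_fraction >= 1) {
    abort_bad_arg("nonlinear and undetectable fractions must be >= 0 and sum to < 1")
  }
  structure(
    list(
      spiked_kinases = tibble::as_tibble(spiked_kinases),
      noise_sd = noise_sd,
      baseline_slope_range = as.double(baseline_slope_range),
      nonlinear_fraction = nonlinear_fraction,
      undetectable_fraction = undetectable_fraction,
      seed = as.integer(seed)
    ),
    class = "synthetic_truth"
  )
}
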