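#' Simulate native-format score tables for the non-resampling pipelines
#'
#' Generates plausible output tables for the three external kinase-scoring
#' pipelines (upstream kinase analysis, phosphosite signature enrichment, and
#' kinase enrichment analysis) from the same spiked ground truth used by
#' [simulate_run()], so the four-pipeline aggregation path can be exercised
#' end to end without the external tools. Kinases belonging to spiked families
#' receive systematically stronger scores (larger absolute median final
#' scores, smaller FDR-type values); each pipeline covers only a random subset
#' of kinases, emulating the differing database coverage that makes some
#' kinases "not reported".
#'
#' These tables emulate only the statistical shape of the external outputs
#' (score orientation, FDR scale, partial coverage), not the tools'
#' algorithms.
#'
#' @param map Kinase-peptide map ([generate_map()]); supplies the kinase and
#'   family roster.
#' @param truth A [synthetic_truth()]; its spiked kinases drive the signal.
#' @param context_id Comparison identifier stamped on every row.
#' @param coverage Fraction of kinases each pipeline reports (default 0.8).
#' @param seed Integer seed.
#' @return Named list of native tables: `uka` (kinase, median final score),
#'   `ptmsea` (kinase, kinase type, `fdr_pvalue_totalGeoMeanLFC`), `kea3`
#'   (kinase x database x LFC cutoff FDR p-values), ready for the
#'   corresponding [adapters].
#' @export
simulate_pipeline_scores <- function(map, truth, context_id,
                                     coverage = 0.8, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"), coverage > 0, coverage <= 1)
  set.seed(derive_seed(seed, 29L))
  roster <- dplyr::distinct(map, .data$kinase_id, .data$family_id)
  spiked_fams <- unique(map$family_id[map$kinase_id %in% truth$spiked_kinases$kinase_id])
  is_hot <- roster$family_id %in% spiked_fams
  n <- nrow(roster)

  pick <- function() {
    keep <- runif(n) < coverage
    if (!any(keep)) keep[sample.int(n, 1L)] <- TRUE
    keep
  }

  k_uka <- pick()
  uka <- tibble::tibble(
    context_id = context_id,
    kinase_id = roster$kinase_id[k_uka],
    median_final_score = rnorm(sum(k_uka), mean = ifelse(is_hot[k_uka], 3, 0), sd = 1)
  )

  k_ptm <- pick()
  ptmsea <- tibble::tibble(
    context_id = context_id,
    kinase_id = roster$kinase_id[k_ptm],
    kinase_type = "TK",
    fdr_pvalue_totalGeoMeanLFC = ifelse(
      is_hot[k_ptm], runif(sum(k_ptm), 0.001, 0.05), runif(sum(k_ptm), 0.05, 1)
    )
  )

  k_kea <- pick()
  kea3 <- tidyr::expand_grid(
    kinase_id = roster$kinase_id[k_kea],
    database = c("ChengKSIN", "PTMsigDB", "PhosDAll"),
    lfc_cutoff = c(0.2, 0.3, 0.4)
  )
  hot_k <- kea3$kinase_id %in% roster$kinase_id[is_hot]
  kea3$fdr <- ifelse(
    hot_k, runif(nrow(kea3), 0.001, 0.05), runif(nrow(kea3), 0.05, 1)
  )
  kea3$context_id <- context_id

  list(uka = uka, ptmsea = ptmsea, kea3 = kea3)
}
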