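test_that("inclusive percentiles span 0-100 with averaged ties", {
  expect_equal(unname(inclusive_percentile_rank(c(1, 2, 3))), c(0, 50, 100))
  expect_equal(unname(inclusive_percentile_rank(c(7, 7, 7))), c(50, 50, 50))
  expect_equal(unname(inclusive_percentile_rank(42)), 100)
  expect_equal(unname(inclusive_percentile_rank(c(1, 5, 5, 9))),
               c(0, 50, 50, 100))
  # Inf sentinel ranks top; NA is an error naming the offender
  expect_equal(unname(inclusive_percentile_rank(c(a = 1, b = Inf)))[2], 100)
  expect_error(inclusive_percentile_rank(c(a = 1, b = NA)), "b")
  # monotone non-decreasing in raw score (property over random draws)
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(25)
    p <- inclusive_percentile_rank(x)
    expect_true(all(diff(p[order(x)]) >= 0))
    expect_true(all(p >= 0 & p <= 100))
  }
})

test_that("pipeline adapters orient scores as evidence strength", {
  # median final score: absolute value
  uka <- adapter_uka(tibble::tibble(
    context_id = "X", kinase_id = c("A", "B", "C"),
    median_final_score = c(-3.2, 0, 4)
  ))
  expect_equal(uka$raw_score, c(3.2, 0, 4))
  p <- inclusive_percentile_rank(
    adapter_uka(tibble::tibble(
      context_id = "X", kinase_id = c("A", "B"),
      median_final_score = c(-5, 4)
    ))$raw_score
  )
  expect_equal(unname(p), c(100, 0))
  expect_error(adapter_uka(tibble::tibble(kinase_id = "A")), "missing")

  # reciprocal FDR-scaled statistic, tyrosine kinases only
  ptm <- adapter_ptmsea(tibble::tibble(
    context_id = "X", kinase_id = c("A", "B", "C"),
    kinase_type = c("TK", "STK", "TK"),
    fdr_pvalue_totalGeoMeanLFC = c(0.5, 0.1, 1.0)
  ))
  expect_equal(ptm$kinase_id, c("A", "C"))
  expect_equal(ptm$raw_score, c(2, 1))
  expect_warning(
    z <- adapter_ptmsea(tibble::tibble(
      context_id = "X", kinase_id = "A", kinase_type = "TK",
      fdr_pvalue_totalGeoMeanLFC = 0
    )),
    "sentinel"
  )
  expect_equal(z$raw_score, Inf)
})

test_that("the enrichment adapter averages cutoffs, then databases, then logs", {
  grid <- tidyr::expand_grid(
    context_id = "X", kinase_id = "A",
    database = c("ChengKSIN", "PTMsigDB", "PhosDAll"),
    lfc_cutoff = c(0.2, 0.3, 0.4)
  )
  expect_equal(adapter_kea3(dplyr::mutate(grid, fdr = 0.1))$raw_score, 1)
  expect_equal(adapter_kea3(dplyr::mutate(grid, fdr = 1))$raw_score, 0)

  per_db <- dplyr::mutate(grid, fdr = dplyr::case_when(
    database == "ChengKSIN" ~ 0.1,
    database == "PTMsigDB" ~ 0.01,
    TRUE ~ 0.001
  ))
  expect_equal(adapter_kea3(per_db)$raw_score, -log10(mean(c(0.1, 0.01, 0.001))),
               tolerance = 1e-12)
  # missing database: averaged over reporting databases, with a warning
  expect_warning(
    partial <- adapter_kea3(per_db[per_db$database != "PhosDAll", ]),
    "missing"
  )
  expect_equal(partial$raw_score, -log10(mean(c(0.1, 0.01))), tolerance = 1e-12)
  expect_error(
    adapter_kea3(dplyr::mutate(grid, database = "Other", fdr = 1)),
    "unknown"
  )
})

test_that("unweighted and weighted averages follow the reporting rules", {
  expect_equal(unweighted_average(c(100, 80)), 90)
  expect_equal(unweighted_average(c(100, NA, NA, NA)), 100)
  expect_equal(unweighted_average(c(96, NA, NA, 98)), 97)
  expect_error(unweighted_average(c(NA_real_, NA_real_)), "report")

  expect_equal(weighted_average(c(87, 95, 36, 82), 4), 75)
  expect_equal(weighted_average(c(100, 77, NA, 90), 4), 66.75)
  expect_equal(round(weighted_average(c(100, 77, NA, 90), 4)), 67)
  v <- c(55, 55, 55, 55)
  expect_equal(weighted_average(v, 4), unweighted_average(v))  # complete: no penalty
  expect_error(weighted_average(c(1, 2), 1), "more reporting")
  expect_error(weighted_average(c(1, 2), 0), "positive")

  # weighted = unweighted x reporting fraction, hence never larger
  set.seed(8)
  for (i in 1:20) {
    p <- runif(4, 0, 100)
    p[sample.int(4, sample(0:3, 1))] <- NA
    if (all(is.na(p))) p[1] <- 50
    expect_equal(weighted_average(p, 4),
                 unweighted_average(p) * sum(!is.na(p)) / 4,
                 tolerance = 1e-12)
    expect_lte(weighted_average(p, 4), unweighted_average(p) + 1e-12)
  }
})

test_that("aggregation is permutation-invariant and annotates families", {
  scores <- tibble::tibble(
    pipeline_id = rep(c("KRSA", "UKA"), each = 3),
    context_id = "X",
    kinase_id = rep(c("A", "B", "C"), 2),
    raw_score = c(3, 2, 1, 10, 30, 20)
  ) |> score_percentiles()
  fams <- tibble::tibble(kinase_id = c("A", "B", "C"), family_id = "F")
  agg <- aggregate_rankings(scores, families = fams)
  shuffled <- aggregate_rankings(scores[sample.int(nrow(scores)), ], families = fams)
  expect_equal(agg, shuffled)
  expect_equal(agg$family_id, rep("F", 3))
  expect_equal(agg$unweighted_avg[agg$kinase_id == "A"], (100 + 0) / 2)
  expect_error(score_percentiles(dplyr::bind_rows(scores, scores[1, ])), "duplicate")
})

test_that("group percentiles are cell-line means, matching brute force", {
  set.seed(77)
  scores <- tidyr::expand_grid(
    pipeline_id = c("KRSA", "UKA"),
    context_id = c("L1", "L2"),
    kinase_id = sprintf("K%02d", 1:12)
  ) |>
    dplyr::mutate(raw_score = runif(dplyr::n())) |>
    dplyr::slice_sample(prop = 0.8) |>            # some kinases unreported somewhere
    score_percentiles()
  grp <- aggregate_groups(scores, list(G = c("L1", "L2")))

  # independent brute-force recomputation over the score table
  for (pl in unique(grp$pipeline_id)) {
    for (kin in unique(grp$kinase_id[grp$pipeline_id == pl])) {
      got <- grp$percentile[grp$pipeline_id == pl & grp$kinase_id == kin]
      want <- mean(scores$percentile[scores$pipeline_id == pl &
                                       scores$kinase_id == kin &
                                       scores$context_id %in% c("L1", "L2")])
      expect_equal(got, want)
    }
  }

  # singleton group reproduces the cell line exactly
  solo <- aggregate_groups(scores, list(S = "L1"))
  l1 <- dplyr::filter(scores, context_id == "L1") |>
    dplyr::arrange(pipeline_id, kinase_id)
  solo <- dplyr::arrange(solo, pipeline_id, kinase_id)
  expect_equal(solo$percentile, l1$percentile)
  expect_equal(solo$kinase_id, l1$kinase_id)

  expect_error(aggregate_groups(scores, list(G = character())), "empty")
  expect_error(aggregate_groups(scores, list(G = "nope")), "unknown")
  expect_error(aggregate_groups(scores, list(c("L1"))), "named")
})

test_that("top-k tables sort, break ties alphabetically, and round halves to even", {
  rankings <- tibble::tibble(
    context_id = "X",
    kinase_id = sprintf("K%02d", 1:12),
    KRSA = c(95.5, 64.5, 70.5, 89.5, 91.5, 50, 40, 30, 20, 10, 5, 1),
    unweighted_avg = c(80, 80, 70.5, 60, 50, 45, 40, 35, 30, 25, 20, 15),
    weighted_avg = c(80, 80, 70.5, 60, 50, 45, 40, 35, 30, 25, 20, 15) / 2
  )
  top <- top_k_table(rankings, k = 10)
  expect_equal(nrow(top), 10L)
  expect_equal(top$kinase_id[1:2], c("K01", "K02"))   # tie broken alphabetically
  expect_equal(top$rank, 1:10)
  expect_equal(top$KRSA[1:5], c(96, 64, 70, 90, 92))  # half-to-even display
  expect_equal(top$unweighted_avg[3], 70)             # 70.5 -> 70
  expect_true(all(diff(top$unweighted_avg_exact) <= 0))
  expect_error(top_k_table(rankings, k = 0), "k")
})

test_that("reference ranking fixtures load with full layout", {
  for (w in c("two_pipeline_average", "two_pipeline_weighted",
              "four_pipeline_average", "four_pipeline_weighted")) {
    tab <- load_reference_rankings(w)
    expect_equal(nrow(tab), 50L)
    expect_setequal(unique(tab$context_id),
                    c("PANC1", "PDCL15", "PDCL5", "Patient-Derived", "All"))
    expect_true(all(tab$rank %in% 1:10))
    npipes <- if (grepl("two", w)) 2L else 4L
    expect_equal(ncol(tab), 5L + npipes)
  }
})
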