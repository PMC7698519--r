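test_that("exact lines and flat series fit as expected", {
  s <- exact_series(slope = 2, intercept = 0)
  fit <- fit_exposure_slope(s$exposure, s$intensity)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r_squared, 1)
  expect_true(fit$detectable)

  flat <- fit_exposure_slope(c(10, 20, 50, 100, 200), rep(5, 5))
  expect_equal(flat$slope, 0)
  expect_false(flat$detectable)

  expect_error(fit_exposure_slope(c(10, 10), c(1, 2)), "distinct")
  expect_error(fit_exposure_slope(c(10, 20), c(1, Inf)), "finite")
})

test_that("slope and R-squared match the normal-equations oracle", {
  x <- c(10, 20, 50, 100, 200)
  y <- c(12, 19, 55, 98, 205)
  # independent closed-form oracle from the normal equations
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  oracle_slope <- sxy / sxx
  oracle_intercept <- mean(y) - oracle_slope * mean(x)
  oracle_r2 <- sxy^2 / (sxx * syy)

  fit <- fit_exposure_slope(x, y)
  expect_equal(fit$slope, oracle_slope, tolerance = 1e-12)
  expect_equal(fit$intercept, oracle_intercept, tolerance = 1e-12)
  expect_equal(fit$r_squared, oracle_r2, tolerance = 1e-12)

  # and against the reference linear-model fitter
  lmfit <- lm(y ~ x)
  expect_equal(fit$slope, unname(coef(lmfit)[2]), tolerance = 1e-12)
  expect_equal(fit$r_squared, summary(lmfit)$r.squared, tolerance = 1e-12)
})

test_that("vectorized run fitting equals per-series fitting", {
  d <- demo_comparison(seed = 13, noise_sd = 25)
  fits <- fit_run_slopes(d$run$intensities)
  some <- fits[sample.int(nrow(fits), 20), ]
  for (i in seq_len(nrow(some))) {
    series <- dplyr::filter(
      d$run$intensities,
      peptide_id == some$peptide_id[i], sample_id == some$sample_id[i]
    )
    single <- fit_exposure_slope(series$exposure_ms, series$intensity)
    expect_equal(some$slope[i], single$slope, tolerance = 1e-10)
    expect_equal(some$r_squared[i], single$r_squared, tolerance = 1e-10)
  }
})

test_that("the retention filter is per-sample, strict at 0.90, and monotone", {
  fits <- tibble::tibble(
    peptide_id = rep(c("pA", "pB", "pC"), each = 2),
    sample_id = rep(c("case_1", "control_1"), 3),
    condition = rep(c("case", "control"), 3),
    replicate = 1L,
    slope = c(1, 1, 1, 1, 1, -0.1),
    intercept = 0,
    r_squared = c(0.95, 0.89, 0.95, 0.96, 1, 1),
    detectable = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  # pA fails R^2 in one sample, pC fails detectability in one sample
  expect_equal(filter_peptides(fits), "pB")
  # boundary: exactly 0.90 is retained
  fits$r_squared[2] <- 0.90
  expect_setequal(filter_peptides(fits), c("pA", "pB"))
  fits$r_squared[2] <- 0.8999
  expect_equal(filter_peptides(fits), "pB")
  # monotone in r2_min
  d <- demo_comparison(seed = 17, noise_sd = 40)
  dfits <- fit_run_slopes(d$run$intensities)
  retained <- lapply(c(0.5, 0.8, 0.9, 0.99), function(t) filter_peptides(dfits, t))
  for (i in seq_len(length(retained) - 1)) {
    expect_true(all(retained[[i + 1]] %in% retained[[i]]))
  }
  expect_equal(filter_peptides(fits[0, ]), character())
})

test_that("internal controls are excluded from the retained set", {
  d <- demo_comparison(seed = 19, noise_sd = 0)
  fits <- fit_run_slopes(d$run$intensities)
  retained <- filter_peptides(fits, catalog = d$catalog)
  controls <- d$catalog$peptide_id[d$catalog$is_internal_control]
  expect_length(intersect(retained, controls), 0L)
  expect_equal(length(retained), 193L)  # all non-control peptides perfect lines
})

test_that("fold changes average replicate ratios and call differentials", {
  fits <- tibble::tibble(
    peptide_id = "p1",
    sample_id = c("case_1", "case_2", "case_3", "control_1", "control_2", "control_3"),
    condition = rep(c("case", "control"), each = 3),
    replicate = rep(1:3, 2),
    slope = c(1.2, 1.3, 1.4, 1, 1, 1),
    intercept = 0, r_squared = 1, detectable = TRUE
  )
  pfc <- compute_fold_change(fits, "p1")
  expect_equal(pfc$fc, 1.3)
  expect_equal(pfc$log2fc, log2(1.3))
  expect_equal(pfc$n_replicates, 3L)
  expect_true(pfc$is_differential)

  # identity: case == control
  fits$slope <- 1
  pfc <- compute_fold_change(fits, "p1")
  expect_equal(pfc$fc, 1)
  expect_equal(pfc$log2fc, 0)
  expect_false(pfc$is_differential)

  # non-positive control slope routes the peptide out, not a crash
  fits$slope <- c(1, 1, 1, 1, 0, 1)
  expect_equal(nrow(compute_fold_change(fits, "p1")), 0L)
})

test_that("per-replicate ratios are reciprocal under condition swap", {
  d <- demo_comparison(seed = 23, noise_sd = 30)
  fits <- fit_run_slopes(d$run$intensities)
  retained <- filter_peptides(fits, catalog = d$catalog)
  swapped <- dplyr::mutate(
    fits, condition = ifelse(condition == "case", "control", "case")
  )
  fwd <- compute_fold_change(fits, retained, average = "geometric")
  rev <- compute_fold_change(swapped, retained, average = "geometric")
  joined <- dplyr::inner_join(fwd, rev, by = "peptide_id")
  expect_gt(nrow(joined), 100)
  expect_equal(joined$fc.x * joined$fc.y, rep(1, nrow(joined)), tolerance = 1e-10)
})

test_that("noise-free differential set equals the strong spiked peptides", {
  catalog <- generate_catalog(seed = 29)
  map <- generate_map(catalog, n_kinases = 40L, seed = 29)
  truth <- synthetic_truth(
    spiked_kinases = tibble::tibble(
      kinase_id = c("KIN01", "KIN02"),
      effect_log2fc = c(1, 0.2)      # 0.2 < log2(1.30): below threshold
    ),
    noise_sd = 0, seed = 29
  )
  run <- simulate_run(catalog, map, truth)
  fits <- fit_run_slopes(run$intensities)
  retained <- filter_peptides(fits, catalog = catalog)
  pfc <- compute_fold_change(fits, retained)
  strong <- unique(map$peptide_id[map$kinase_id == "KIN01"])
  weak_only <- setdiff(unique(map$peptide_id[map$kinase_id == "KIN02"]), strong)
  expect_setequal(pfc$peptide_id[pfc$is_differential], strong)
  expect_true(all(!pfc$is_differential[pfc$peptide_id %in% weak_only]))
})

test_that("differential thresholds are inclusive and validated", {
  expect_true(call_differential(1.30))
  expect_true(call_differential(0.70))
  expect_false(call_differential(1.29))
  expect_false(call_differential(0.71))
  expect_false(call_differential(1.00))
  expect_error(call_differential(1.2, up = 0.5, down = 0.7), "exceed")
  expect_error(call_differential(-1), "positive")
})
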