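#' Fit the exposure slope of one peptide series
#'
#' Ordinary least squares of fluorescence intensity on camera exposure time,
#' with intercept. The slope is the peptide phosphorylation intensity signal;
#' the coefficient of determination (R-squared) measures linearity. A peptide
#' is `detectable` only if its slope is positive and its maximum intensity
#' reaches `intensity_floor`.
#'
#' If the intensities are exactly constant (zero total sum of squares),
#' R-squared is defined as 1 when the fit is exact and 0 otherwise; such a
#' series has slope 0 and is undetectable regardless.
#'
#' @param exposure Numeric vector of exposure times (ms); >= 2 distinct values.
#' @param intensity Numeric vector of intensities, finite, same length.
#' @param intensity_floor Detection floor on the maximum intensity (default 0).
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`, `detectable`.
#' @examples
#' fit_exposure_slope(c(10, 20, 50, 100, 200), c(20, 40, 100, 200, 400))
#' @export
fit_exposure_slope <- function(exposure, intensity, intensity_floor = 0) {
  if (length(exposure) != length(intensity)) {
    abort_bad_arg("`exposure` and `intensity` must have equal length")
  }
  if (length(unique(exposure)) < 2L) {
    abort_bad_arg("need at least 2 distinct exposure values")
  }
  if (!all(is.finite(intensity))) {
    abort_bad_arg("intensities must be finite")
  }
  xm <- mean(exposure)
  ym <- mean(intensity)
  sxx <- sum((exposure - xm)^2)
  sxy <- sum((exposure - xm) * (intensity - ym))
  slope <- sxy / sxx
  intercept <- ym - slope * xm
  sst <- sum((intensity - ym)^2)
  ssr <- sum((intensity - intercept - slope * exposure)^2)
  r2 <- if (sst <= .Machine$double.eps * max(1, ym^2)) {
    if (ssr <= .Machine$double.eps) 1 else 0
  } else {
    max(0, min(1, 1 - ssr / sst))
  }
  tibble::tibble(
    slope = slope,
    intercept = intercept,
    r_squared = r2,
    detectable = slope > 0 && max(intensity) >= intensity_floor
  )
}

#' Fit exposure slopes for every peptide series in a run
#'
#' Vectorized closed-form least squares over all (sample, peptide) series of a
#' long-format intensity table, equivalent to calling [fit_exposure_slope()]
#' per series.
#'
#' @param intensities Long tibble with columns `sample_id`, `condition`,
#'   `replicate`, `peptide_id`, `exposure_ms`, `intensity` (as produced by
#'   [simulate_run()] or [read_run_tsv()]).
#' @param intensity_floor Detection floor (see [fit_exposure_slope()]).
#' @return Tibble with one row per (sample, peptide): `peptide_id`,
#'   `sample_id`, `condition`, `replicate`, `slope`, `intercept`, `r_squared`,
#'   `detectable`.
#' @export
fit_run_slopes <- function(intensities, intensity_floor = 0) {
  req <- c("sample_id", "condition", "replicate", "peptide_id", "exposure_ms", "intensity")
  if (!all(req %in% names(intensities))) {
    abort_bad_arg(sprintf("intensity table must have columns: %s", paste(req, collapse = ", ")))
  }
  if (!all(is.finite(intensities$intensity))) {
    abort_bad_arg("intensities must be finite")
  }
  eps <- .Machine$double.eps
  intensities |>
    dplyr::group_by(.data$peptide_id, .data$sample_id, .data$condition, .data$replicate) |>
    dplyr::summarise(
      .n_exp = length(unique(.data$exposure_ms)),
      .sxx = sum((.data$exposure_ms - mean(.data$exposure_ms))^2),
      slope = sum((.data$exposure_ms - mean(.data$exposure_ms)) *
                    (.data$intensity - mean(.data$intensity))) / .data$.sxx,
      intercept = mean(.data$intensity) - .data$slope * mean(.data$exposure_ms),
      .sst = sum((.data$intensity - mean(.data$intensity))^2),
      .ssr = sum((.data$intensity - .data$intercept - .data$slope * .data$exposure_ms)^2),
      r_squared = dplyr::if_else(
        .data$.sst <= eps * pmax(1, mean(.data$intensity)^2),
        dplyr::if_else(.data$.ssr <= eps, 1, 0),
        pmax(0, pmin(1, 1 - .data$.ssr / .data$.sst))
      ),
      detectable = .data$slope > 0 & max(.data$intensity) >= intensity_floor,
      .groups = "drop"
    ) |>
    (\(d) {
      if (any(d$.n_exp < 2L)) {
        abort_bad_arg("every series needs at least 2 distinct exposure values")
      }
      d
    })() |>
    dplyr::select(
      "peptide_id", "sample_id", "condition", "replicate",
      "slope", "intercept", "r_squared", "detectable"
    )
}

#' Select peptides passing the linearity and detectability filter
#'
#' A peptide is retained only if, in every sample of the comparison, its fit
#' has `r_squared >= r2_min` and is detectable (positive slope above the
#' intensity floor). Internal-control peptides are excluded from downstream
#' differential calling when a catalog is supplied.
#'
#' Raising `r2_min` can only shrink the retained set (monotone filtering).
#'
#' @param fits Slope-fit table from [fit_run_slopes()].
#' @param r2_min Minimum R-squared (default 0.90, inclusive).
#' @param catalog Optional peptide catalog used to drop internal controls.
#' @return Sorted character vector of retained peptide ids (empty input gives
#'   an empty set).
#' @export
filter_peptides <- function(fits, r2_min = 0.90, catalog = NULL) {
  if (nrow(fits) == 0L) {
    return(character())
  }
  keep <- fits |>
    dplyr::group_by(.data$peptide_id) |>
    dplyr::summarise(
      ok = all(.data$r_squared >= r2_min & .data$detectable),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$ok) |>
    dplyr::pull("peptide_id")
  if (!is.null(catalog)) {
    keep <- setdiff(keep, catalog$peptide_id[catalog$is_internal_control])
  }
  sort(keep)
}

#' Replicate-averaged peptide fold changes
#'
#' Pairs case and control samples by replicate index, computes the
#' per-replicate fold change of exposure slopes (case / control), and averages
#' across replicates — by default on the ratio scale (arithmetic mean of FCs),
#' with a geometric-mean alternative. Peptides whose control slope is not
#' strictly positive in any replicate are dropped (routed to the exclusion
#' set, not an error), as the ratio is undefined.
#'
#' @param fits Slope-fit table from [fit_run_slopes()] covering both
#'   conditions.
#' @param retained Character vector of peptide ids surviving
#'   [filter_peptides()].
#' @param average `"arithmetic"` (default) or `"geometric"` replicate
#'   averaging of fold changes.
#' @param fc_up,fc_down Differential thresholds passed to
#'   [call_differential()].
#' @return Tibble with one row per retained, computable peptide: `peptide_id`,
#'   `fc`, `log2fc`, `n_replicates`, `is_differential`.
#' @export
compute_fold_change <- function(fits, retained,
                                average = c("arithmetic", "geometric"),
                                fc_up = 1.30, fc_down = 0.70) {
  average <- match.arg(average)
  wide <- fits |>
    dplyr::filter(.data$peptide_id %in% retained) |>
    dplyr::select("peptide_id", "condition", "replicate", "slope") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "slope")
  if (nrow(wide) > 0L && !all(c("case", "control") %in% names(wide))) {
    abort_bad_arg("fits must contain both 'case' and 'control' conditions")
  }
  if (nrow(wide) == 0L) {
    return(tibble::tibble(
      peptide_id = character(), fc = double(), log2fc = double(),
      n_replicates = integer(), is_differential = logical()
    ))
  }
  wide |>
    dplyr::filter(!is.na(.data$case), !is.na(.data$control)) |>
    dplyr::group_by(.data$peptide_id) |>
    dplyr::filter(all(.data$control > 0)) |>
    dplyr::summarise(
      fc = if (average == "arithmetic") {
        mean(.data$case / .data$control)
      } else {
        exp(mean(log(.data$case / .data$control)))
      },
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      log2fc = log2(.data$fc),
      is_differential = call_differential(.data$fc, up = fc_up, down = fc_down)
    ) |>
    dplyr::select("peptide_id", "fc", "log2fc", "n_replicates", "is_differential")
}

#' Call a peptide differential from its fold change
#'
#' A peptide is differentially phosphorylated when its replicate-averaged fold
#' change is at least `up` or at most `down`; both thresholds are inclusive
#' (the defaults flag signal changes of 30% or more: FC >= 1.30 or FC <= 0.70).
#'
#' @param fc Positive fold change(s).
#' @param up,down Inclusive thresholds; requires `up > down`.
#' @return Logical vector.
#' @examples
#' call_differential(c(1.30, 0.70, 1.00)) # TRUE TRUE FALSE
#' @export
call_differential <- function(fc, up = 1.30, down = 0.70) {
  if (up <= down) {
    abort_bad_arg("`up` threshold must exceed `down` threshold")
  }
  if (any(!is.finite(fc) | fc <= 0)) {
    abort_bad_arg("fold changes must be positive and finite")
  }
  fc >= up | fc <= down
}
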