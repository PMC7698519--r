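#' Inclusive percentile ranks
#'
#' Converts raw scores to percentiles on the closed interval \[0, 100\]:
#' for `n` values sorted ascending the value at ascending rank `r` receives
#' `100 * (r - 1) / (n - 1)`, so the minimum scores 0 and the maximum scores
#' 100 ("inclusive" of both endpoints). Tied values share the mean of their
#' positional percentiles. A single value receives 100. `Inf` is accepted (it
#' ranks top, used as a sentinel for degenerate reciprocal scores); `NA` and
#' `NaN` are errors.
#'
#' Larger raw score must mean stronger evidence; the pipeline adapters
#' guarantee this orientation.
#'
#' @param x Numeric vector of raw scores (optionally named).
#' @return Numeric vector of percentiles in \[0, 100\], names preserved.
#' @examples
#' inclusive_percentile_rank(c(a = 1, b = 2, c = 3)) # 0, 50, 100
#' inclusive_percentile_rank(c(5, 5, 5))             # all 50
#' @export
inclusive_percentile_rank <- function(x) {
  if (length(x) == 0L) {
    abort_bad_arg("`x` must contain at least one score")
  }
  bad <- is.na(x) | is.nan(x)
  if (any(bad)) {
    offenders <- if (!is.null(names(x))) names(x)[bad] else which(bad)
    abort_bad_arg(sprintf(
      "non-finite scores for: %s", paste(offenders, collapse = ", ")
    ))
  }
  n <- length(x)
  if (n == 1L) {
    return(setNames(100, names(x)))
  }
  r <- rank(x, ties.method = "average")
  setNames(100 * (r - 1) / (n - 1), names(x))
}
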