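#' @keywords internal
#' @noRd
abort_bad_arg <- function(msg) {
  stop(msg, call. = FALSE)
}

#' Check a scalar count argument
#' @noRd
check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x) || x < min) {
    abort_bad_arg(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

#' Derive a per-stage substream seed from a global seed.
#'
#' Keeps derived seeds inside the 32-bit integer range so they remain valid
#' arguments to `set.seed()`.
#' @noRd
derive_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 1009 + stage) %% .Machine$integer.max)
}

#' Round to integer percent, halves to even
#'
#' Display rounding used by the ranking tables: round-half-to-even (the IEEE
#' default implemented by [base::round()]), so 95.5 -> 96 and 70.5 -> 70.
#' @noRd
round_percent <- function(x) round(x)
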