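#' Round half away from zero to a fixed number of decimals
#'
#' Commercial ("half-up") rounding, unlike [base::round()]'s banker's
#' rounding: `round_half_up(0.25, 1)` is `0.3`. Used for the modulated
#' receptor percentages, which are reported to one decimal place.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(100 * 13 / 43, 1) # 30.2
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  # nudge by a relative epsilon so values that are exactly .5 in decimal but
  # land a hair below it in binary (e.g. 40.90909...) still round up
  floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale * sign(x)
}

#' Derive a child seed from a run seed
#'
#' One run-level seed fans out to per-generator streams via fixed offsets, so
#' adding a generator never shifts the streams of existing ones. Result is
#' kept inside the positive 32-bit integer range.
#'
#' @param seed integer run seed.
#' @param offset non-negative integer stream offset.
#' @return an integer seed.
#' @export
child_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) * 7919 + offset * 104729) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_val <- function(...) stop(..., call. = FALSE)
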