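#' Round half away from zero
#'
#' Base `round()` rounds half to even; published area tables round half away
#' from zero, so reported values use this rule.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1, the printed precision of
#'   areas in mm^2).
#' @return Numeric vector rounded to `digits` decimals.
#' @export
#' @examples
#' round_half_up(c(0.05, -0.05, 1879.56), 1)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# internal: stop with a classed condition so callers/tests can be specific
abort_pisa <- function(msg, class) {
  rlang::abort(msg, class = c(class, "pisacalc_error"))
}
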