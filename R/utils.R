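#' @importFrom rlang .data %||%
NULL

#' Round half away from zero
#'
#' Base `round()` rounds half to even; the framework's reported percentages
#' use the conventional half-up rule (e.g. 22.15 -> 22.2 at one decimal).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # eps guard: decimal halves (e.g. 22.15) are stored minutely below the
  # half and would otherwise round down
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}
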