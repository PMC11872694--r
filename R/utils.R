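#' Round half away from zero
#'
#' Commercial ("half-up") rounding used for all reported values: ties are
#' rounded away from zero, so 0.085 -> 0.09 and -0.615 -> -0.62. Base
#' [round()] rounds half to even and would disagree with printed survey
#' tables on tie cases.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector rounded to `digits` places.
#' @examples
#' round_half_up(c(2.705, 0.085, -0.615))
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # nudge by machine epsilon so values that are exactly .5 in decimal but
  # stored a hair below it in binary still round up
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
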