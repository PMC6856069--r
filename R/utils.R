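# shared helpers

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.25 -> 0.3 at one digit), as used for
#' the printed specificity percentages. Base [round()] uses banker's rounding,
#' which disagrees on exact halves.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (may be 0).
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x == floor(x)
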