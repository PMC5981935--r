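#' Round half away from zero
#'
#' Commercial rounding: ties go away from zero (`round_half_away(0.5) == 1`,
#' `round_half_away(-0.5) == -1`), unlike [base::round()] which rounds half
#' to even.  All presentation rounding in this package uses this convention,
#' which is the one the published timing and cost tables follow.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimal places.
#' @export
#' @examples
#' round_half_away(c(0.735, -1.025, 2.5), 2)
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  # small epsilon absorbs binary-representation error in values such as
  # 73.6 = 0.8 * 0.92 * 100 that sit a hair below the tie point
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# internal: stop with the caller-supplied message if cond is not TRUE
check_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# internal: scalar non-negative finite number
check_nonneg_scalar <- function(x, name) {
  check_that(is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0,
             sprintf("'%s' must be a single non-negative number", name))
}

# internal: scalar in [0, 1]
check_fraction <- function(x, name) {
  check_that(is.numeric(x) && length(x) == 1 && is.finite(x) &&
               x >= 0 && x <= 1,
             sprintf("'%s' must be a single number in [0, 1]", name))
}
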