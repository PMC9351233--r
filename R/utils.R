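# Shared helpers.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; coverage normalization uses the
#' conventional "round half away from zero" so that scaled counts never lose
#' a full read at the .5 boundary.
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @keywords internal
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Stop unless `cond`; message built with sprintf.
#' @keywords internal
assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}
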