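#' Round half away from zero
#'
#' Display rounding used throughout the trial summaries: ties round away
#' from zero (so 82.5 -> 83, -0.5 -> -1), unlike [base::round()]'s
#' round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_quantavax <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "quantavax_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

assert_finite_numeric <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop_quantavax(sprintf("%s must be finite numeric", what), "quantavax_value_error")
  }
  invisible(x)
}
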