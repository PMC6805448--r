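#' Round half away from zero
#'
#' Presentation rounding used for reported heritabilities and correlations:
#' ties at 5 in the first dropped digit round away from zero (so 0.175 -> 0.18
#' and -0.945 -> -0.95), unlike [base::round()]'s banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_up(0.265, 2)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # nudge by an ulp so values that are exactly x.5 after decimal representation
  # error (e.g. 2.14/12.52*100 = 17.0926...) are not misclassified
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_beeval <- function(msg, class) {
  abort(msg, class = c(class, "beeval_error"))
}

# single scalar check helper
assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_beeval(sprintf("`%s` must be a single finite number.", name),
                "beeval_bad_argument")
  }
  invisible(x)
}
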