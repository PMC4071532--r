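#' @keywords internal
"_PACKAGE"

## Classed conditions so callers can test failure modes programmatically.
mp_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "megapast_error")))
}

mp_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "megapast_warning")))
}

#' Round half away from zero
#'
#' Fixed rounding convention for converting expected counts to integers
#' (base R `round()` rounds half to even, which is seed-hostile in tests).
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

## Deterministic child seeds: keep everything below 2^31 - 1.
derive_seed <- function(seed, offset) {
  (as.numeric(seed) * 48271 + as.numeric(offset)) %% 2147483629
}

`%||%` <- function(a, b) if (is.null(a)) b else a
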