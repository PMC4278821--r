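#' Round half away from zero
#'
#' Base [round()] rounds half to even; survey reports conventionally round
#' half up. A tiny offset guards against values such as `2528.7999...9`
#' produced by binary floating point.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
#' @examples
#' round_half_up(0.125, 2) # 0.13, where round() gives 0.12
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# stop() with a sprintf-style message, without the call in the condition
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Seed the session RNG only when the caller asked for reproducibility.
set_seed_if <- function(seed) {
  if (!is.null(seed)) {
    if (seed != round(seed)) abort("`seed` must be an integer")
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}
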