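#' Construct a sampling scheme
#'
#' A scheme couples a spatial design (which microhabitats of a plot carry a
#' detector) with a temporal pattern (which part of the night is recorded).
#'
#' @param design nonempty subset of [BAT_MICROHABITATS] (short codes accepted).
#' @param pattern one of [BAT_PATTERNS].
#' @return object of class `sampling_scheme`.
#' @export
sampling_scheme <- function(design, pattern) {
  design <- normalize_microhabitat(design)
  if (length(design) == 0 || anyNA(design) || anyDuplicated(design)) {
    abort("`design` must be a nonempty set of distinct microhabitats")
  }
  design <- BAT_MICROHABITATS[BAT_MICROHABITATS %in% design]
  pattern <- match.arg(pattern, BAT_PATTERNS)
  out <- list(design = design, pattern = pattern)
  class(out) <- "sampling_scheme"
  out
}

.mh_code <- c(GROUND = "GR", CANOPY = "CA", GAP = "GA")

#' @export
format.sampling_scheme <- function(x, ...) {
  paste0(paste(.mh_code[x$design], collapse = "+"), " / ", x$pattern)
}

#' @export
print.sampling_scheme <- function(x, ...) {
  cat("Sampling scheme:", format(x), "\n")
  invisible(x)
}

#' Scheme label used in output tables
#' @param scheme a `sampling_scheme`.
#' @return character label such as `"GA+GR / FULL_NIGHT"`.
#' @export
scheme_label <- function(scheme) format(scheme)

#' Enumerate all candidate sampling schemes
#'
#' The seven nonempty designs over three microhabitats crossed with the
#' three temporal patterns: 21 schemes, in deterministic order (singletons,
#' then pairs, then the full design; patterns in the order of
#' [BAT_PATTERNS]).
#'
#' @return list of 21 `sampling_scheme` objects.
#' @export
enumerate_schemes <- function() {
  designs <- list(
    "GROUND", "CANOPY", "GAP",
    c("GROUND", "CANOPY"), c("GAP", "GROUND"), c("GAP", "CANOPY"),
    c("GAP", "GROUND", "CANOPY")
  )
  out <- list()
  for (d in designs) {
    for (p in BAT_PATTERNS) out[[length(out) + 1L]] <- sampling_scheme(d, p)
  }
  out
}
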