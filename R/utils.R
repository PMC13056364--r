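#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. `seed = NULL` leaves the current stream untouched.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

stop2 <- function(...) stop(..., call. = FALSE)

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# mark an object as degenerate (empty mask, constant image, ...)
set_degenerate <- function(x, flag = TRUE) {
  attr(x, "degenerate") <- flag
  x
}

#' Was a result flagged degenerate?
#'
#' Several operations (preprocessing a constant image, scoring an empty mask,
#' metrics with an empty denominator) return a well-defined fallback value
#' instead of failing mid-batch; the fallback carries a `degenerate`
#' attribute that this helper reads.
#'
#' @param x An object returned by an `omapquant` operation.
#' @return `TRUE` if `x` was flagged degenerate, otherwise `FALSE`.
#' @export
is_degenerate <- function(x) isTRUE(attr(x, "degenerate"))
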