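# Shared helpers. Rounding is half-up (not banker's) so that printed report
# values such as "96.5x" or "99.1%" are reproduced from raw inputs.

#' Round half-up to a fixed number of decimals
#'
#' Base R's `round()` rounds half to even; genome reports conventionally round
#' half away from zero. Used by all percentage/fold formatting in the package.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(0.125, 2)  # 0.13, where round() gives 0.12
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# positive scalar check used by parameter validation throughout
.check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("'", name, "' must be a single finite number", call. = FALSE)
  }
  if (strict_lower && x <= lower) {
    stop("'", name, "' must be > ", lower, call. = FALSE)
  }
  if (!strict_lower && x < lower) {
    stop("'", name, "' must be >= ", lower, call. = FALSE)
  }
  if (x > upper) stop("'", name, "' must be <= ", upper, call. = FALSE)
  invisible(x)
}

.methylation_contexts <- c("CG", "CHG", "CHH")
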