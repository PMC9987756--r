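#' @keywords internal
"_PACKAGE"

#' @importFrom stats cmdscale cor median pnorm rgamma rmultinom rnorm runif sd var
#' @importFrom utils read.delim write.table
NULL

# Round half away from zero (base round() is banker's rounding).  All callers
# pass non-negative values, for which half-away-from-zero == half-up.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Run `expr` under a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

stop_ko <- function(...) stop(..., call. = FALSE)

check_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min)
    stop_ko(sprintf("'%s' must be a single finite number >= %s", name, min))
  invisible(x)
}
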