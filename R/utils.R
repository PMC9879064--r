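`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert micrometres to centimetres
#'
#' Convenience for the package's canonical length unit (cm): layer
#' thicknesses and sensor depths are usually quoted in micrometres.
#'
#' @param x length in micrometres.
#' @return length in centimetres.
#' @export
#' @examples
#' um(500)  # 0.05 cm
um <- function(x) x * 1e-4

stop_domain <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain(sprintf("'%s' must be a single finite number", name))
  if (strict_lower && x <= lower)
    stop_domain(sprintf("'%s' must be > %g (got %g)", name, lower, x))
  if (!strict_lower && x < lower)
    stop_domain(sprintf("'%s' must be >= %g (got %g)", name, lower, x))
  if (strict_upper && x >= upper)
    stop_domain(sprintf("'%s' must be < %g (got %g)", name, upper, x))
  if (!strict_upper && x > upper)
    stop_domain(sprintf("'%s' must be <= %g (got %g)", name, upper, x))
  invisible(x)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. All stochastic steps in the package flow
# through this helper so a single explicit seed governs them.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}
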