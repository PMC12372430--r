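#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the
#' caller's RNG state, so seeded package functions never disturb user
#' simulations. A `NULL` seed evaluates `code` under the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Round half away from zero
#'
#' Spreadsheet-style `ROUND(x; 0)` semantics: 0.5 rounds to 1, -0.5 to -1.
#' R's `round()` uses banker's rounding, which would change converted
#' crosswalk scores at exact halves.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 0).
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stop_pc <- function(...) stop(..., call. = FALSE)

# default quadrature grid: 61 equally spaced nodes on [-6, 6] with
# standard-normal weights, the identification scale of all calibrations
theta_grid <- function(n = 61L, bounds = c(-6, 6)) {
  nodes <- seq(bounds[1], bounds[2], length.out = n)
  w <- stats::dnorm(nodes)
  list(nodes = nodes, weights = w / sum(w))
}
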