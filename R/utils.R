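# Shared helpers: classed conditions and seed plumbing.

rader_abort <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("rader_error_", class), "rader_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that library code never leaks
#' RNG state into the caller's session. All stochastic operations in the
#' package take explicit seeds and route through this helper.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    rader_abort("`seed` must be a single integer", "config")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive independent sub-seeds from one master seed
#'
#' One global seed deterministically fans out into per-stage seeds so a
#' whole run is reproducible from a single knob. Derived seeds stay
#' below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n))
}

# scalar checks -------------------------------------------------------------

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
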