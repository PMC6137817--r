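#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded internals do not
#' perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a plain message (no call)
#' @noRd
fail <- function(...) stop(..., call. = FALSE)

#' Check a scalar is a positive finite number
#' @noRd
is_pos_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0
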