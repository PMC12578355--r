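# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package functions never disturb
#' the caller's random-number stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a vector of child seeds from one master seed, all < 2^31.
derive_seeds <- function(master_seed, n) {
  with_local_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_config <- function(...) stop(structure(
  class = c("affectsig_config_error", "error", "condition"),
  list(message = paste0(...), call = sys.call(-1))))

stop_data <- function(...) stop(structure(
  class = c("affectsig_data_error", "error", "condition"),
  list(message = paste0(...), call = sys.call(-1))))

`%||%` <- function(a, b) if (is.null(a)) b else a
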