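# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed and integer indices
#'
#' Counter-based splitting: each (index path) gets its own stream, so changing
#' e.g. the number of wells never reshuffles the draws of other wells.
#' The result is always a valid 32-bit integer seed.
#'
#' @param seed master integer seed
#' @param ... integer indices identifying the stream (strain, hour, well, ...)
#' @return an integer seed
#' @export
split_seed <- function(seed, ...) {
  ix <- c(...)
  h <- (as.double(seed) %% 2147483647) + 1
  for (k in ix) {
    h <- (h * 48271 + as.double(k) + 1) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so package functions never clobber user randomness.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# stopifnot with a readable message
.assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
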