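#' @importFrom stats rnorm runif median quantile sd var predict setNames
#' @importFrom utils head tail write.table read.delim
NULL

# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
# All stochastic operations in the package funnel through this so that a
# `seed` argument gives bit-identical results without clobbering global state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Derive a child seed from a parent seed and a stream index, staying well
# inside 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 2654435761 + 97 * as.double(k)) %% 2147483647L) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
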