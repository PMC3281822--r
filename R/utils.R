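`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded at `seed` and
#' restores the caller's RNG state afterwards, so seeded helpers do not
#' disturb an enclosing simulation stream. With `seed = NULL` the code simply
#' uses (and advances) the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible child seed from a master seed
#'
#' Mixes a master seed with one or more integer indices (replicate number,
#' grid-cell index, window start, ...) through a multiplicative congruential
#' step so every replicate and window gets its own deterministic stream.
#' Results stay inside the 32-bit integer range R requires of seeds.
#'
#' @param seed Master integer seed.
#' @param ... Integer indices to mix in, in order.
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(1, 3, 7)
derive_seed <- function(seed, ...) {
  ks <- c(...)
  x <- as.double(seed) %% 2147483629
  for (k in ks) x <- (x * 48271 + (as.double(k) + 1) * 7919) %% 2147483629
  as.integer(x)
}
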