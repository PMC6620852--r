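# Shared helpers: seeded evaluation, padding, activations.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded generators do not disturb the caller's
#' random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Reflect-101 index vector: positions 1..n_out map into 1..n with `before`
# padded elements mirrored about the first/last element (edge not repeated).
# Requires before, after <= n - 1.
reflect_index <- function(n, before, after) {
  k <- seq_len(n + before + after) - before
  k[k < 1] <- 2 - k[k < 1]
  k[k > n] <- 2 * n - k[k > n]
  k
}

# Pad a (H, W) matrix or (H, W, C) array by reflection to the given total
# size, placing the original with `top`/`left` offset.
pad_reflect <- function(x, top, bottom, left, right) {
  d <- dim(x)
  ri <- reflect_index(d[1], top, bottom)
  ci <- reflect_index(d[2], left, right)
  if (length(d) == 2) x[ri, ci, drop = FALSE] else x[ri, ci, , drop = FALSE]
}

# Clamp numeric values into [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_if_not_binary <- function(x, name) {
  if (!all(x %in% c(0, 1)))
    stop(sprintf("`%s` must be a binary (0/1) matrix", name), call. = FALSE)
}

as_cube <- function(x) {
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1L)
  x
}
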