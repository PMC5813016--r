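# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state on exit.
# All stochastic stages in the package route their randomness through this so
# that a given seed yields bit-identical output regardless of ambient state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stopifnot_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (nonneg && x < 0) stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  invisible(x)
}

# Offsets (drow, dcol) of a discrete disk: Euclidean radius test, centre
# included. Used as the structuring element for erosion/dilation/top-hat.
disk_offsets <- function(radius) {
  stopifnot_scalar_num(radius, "radius", positive = TRUE)
  r <- as.integer(radius)
  g <- expand.grid(drow = -r:r, dcol = -r:r)
  g <- g[g$drow^2 + g$dcol^2 <= radius^2, , drop = FALSE]
  as.matrix(g)
}

is_uint16 <- function(x) {
  is.matrix(x) && is.numeric(x) && !anyNA(x) &&
    all(x >= 0 & x <= 65535) && all(x == floor(x))
}
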