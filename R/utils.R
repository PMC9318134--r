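# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched. All exported stochastic functions route their
# randomness through this, so a seed argument fully determines the output
# and no global state leaks.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive reproducible sub-seeds from a master seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Coerce a field or raw raster to an H x W x 3 integer image array.
as_ihc_image <- function(x) {
  if (inherits(x, "synthetic_field")) x <- x$image
  if (!(is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L)) {
    stop("expected an H x W x 3 RGB image array (8-bit channels)")
  }
  x
}

# Map a continuous 0-based (row, col) coordinate to 1-based pixel indices.
# Pixel i (0-based) spans [i, i+1) with its center at i + 0.5, so a point
# maps to the pixel containing it — the nearest pixel center. Coordinates
# exactly on an integer pixel boundary resolve DOWN to the lower pixel.
# Every pixel's preimage has width exactly 1, which keeps uniform-random
# point sampling unbiased.
point_to_pixel <- function(coord, extent_dim) {
  px1 <- pmax(ceiling(coord), 1)
  as.integer(pmin(px1, extent_dim))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
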