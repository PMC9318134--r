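# Synthetic IHC field generation: DAB-brown blobs on a hematoxylin-style
# background, with an exact ground-truth mask.

IHC_MARKERS <- c("CD3", "CD4", "CD8", "CD15", "CD20", "CD68", "CD138")

# Default palette. Chosen so that in the clean (GOOD) regime every
# non-stained pixel is farther than 100 (Chebyshev, per 8-bit channel) from
# the DAB reference brown even after per-pixel jitter: color-range selection
# at the default fuzziness then recovers the truth mask exactly.
DEFAULT_STAIN_COLOR <- c(120L, 66L, 18L)
DEFAULT_PALETTE <- list(
  background = c(205L, 205L, 230L),  # pale hematoxylin wash
  nucleus    = c(80L, 80L, 140L),    # hematoxylin-dark nuclei
  eosin      = c(230L, 185L, 205L)   # pink connective-tissue patches
)

#' Generation parameters for a synthetic IHC field
#'
#' Bundles the tunable knobs of [generate_field()]. The defaults render a
#' 512 x 512 field with DAB-brown elliptical cell blobs
#' (RGB `c(120, 66, 18)` with +/-10 per-channel jitter) on a pale
#' hematoxylin background with darker nucleus ellipses and eosin-pink
#' patches; all palette colors are constructed to stay outside the brown
#' color family so that, in the GOOD regime, the stained pixels are
#' exactly the ground-truth mask.
#'
#' @param extent integer vector `c(height, width)` in pixels (>= 32 each).
#' @param target_fraction desired stained-area percentage in \[0, 100\].
#' @param blob_axes range `c(min, max)` of ellipse semi-axes, pixels.
#' @param stain_color RGB triple (8-bit) of the specific stain.
#' @param stain_jitter max absolute per-channel jitter inside blobs.
#' @param background_palette list with `background`, `nucleus`, `eosin`
#'   RGB triples.
#' @param seed integer seed; fully determines the output.
#' @return An object of class `field_gen_params`.
#' @export
field_gen_params <- function(extent = c(512L, 512L),
                             target_fraction = 15,
                             blob_axes = c(5, 16),
                             stain_color = DEFAULT_STAIN_COLOR,
                             stain_jitter = 10L,
                             background_palette = DEFAULT_PALETTE,
                             seed = 1L) {
  stopifnot(
    length(extent) == 2L, all(extent >= 32L),
    length(target_fraction) == 1L,
    target_fraction >= 0, target_fraction <= 100,
    length(blob_axes) == 2L, all(blob_axes > 0), blob_axes[1] <= blob_axes[2],
    length(stain_color) == 3L, all(stain_color >= 0 & stain_color <= 255)
  )
  structure(
    list(
      extent = as.integer(extent),
      target_fraction = as.numeric(target_fraction),
      blob_axes = as.numeric(blob_axes),
      stain_color = as.integer(stain_color),
      stain_jitter = as.integer(stain_jitter),
      background_palette = background_palette,
      seed = as.integer(seed)
    ),
    class = "field_gen_params"
  )
}

# Rasterize one ellipse; returns linear pixel indices into an H x W matrix.
ellipse_pixels <- function(center, axes, theta, H, W) {
  r0 <- center[1]; c0 <- center[2]
  a <- axes[1]; b <- axes[2]
  rmax <- ceiling(max(a, b))
  rows <- max(1L, floor(r0 - rmax)):min(H, ceiling(r0 + rmax))
  cols <- max(1L, floor(c0 - rmax)):min(W, ceiling(c0 + rmax))
  if (!length(rows) || !length(cols)) return(integer(0))
  dr <- rows - r0
  dc <- cols - c0
  ct <- cos(theta); st <- sin(theta)
  u <- outer(dr, dc, function(x, y) (x * ct + y * st) / a)
  v <- outer(dr, dc, function(x, y) (-x * st + y * ct) / b)
  inside <- which(u * u + v * v <= 1)
  if (!length(inside)) return(integer(0))
  ri <- rows[(inside - 1L) %% length(rows) + 1L]
  ci <- cols[(inside - 1L) %/% length(rows) + 1L]
  (ci - 1L) * H + ri
}

# Grow a blob mask to exactly `n_target` pixels. The last blob placed is
# trimmed farthest-from-center-first so the hit count is exact.
build_blob_mask <- function(H, W, n_target, blob_axes) {
  mask <- matrix(0L, H, W)
  if (n_target == 0L) return(mask)
  total <- H * W
  if (n_target == total) return(matrix(1L, H, W))
  count <- 0L
  mean_area <- max(1, pi * mean(blob_axes)^2)
  max_blobs <- max(2000L, ceiling(30 * n_target / mean_area))
  iter <- 0L
  while (count < n_target) {
    iter <- iter + 1L
    if (iter > max_blobs) {
      stop(sprintf(
        paste0("could not reach target fraction: %d of %d pixels stained ",
               "after %d blobs (semi-axes in [%g, %g]); enlarge blob_axes ",
               "or lower target_fraction"),
        count, n_target, max_blobs, blob_axes[1], blob_axes[2]
      ))
    }
    center <- c(runif(1, 1, H), runif(1, 1, W))
    axes <- runif(2, blob_axes[1], blob_axes[2])
    theta <- runif(1, 0, pi)
    idx <- ellipse_pixels(center, axes, theta, H, W)
    new_idx <- idx[mask[idx] == 0L]
    if (!length(new_idx)) next
    overshoot <- count + length(new_idx) - n_target
    if (overshoot > 0L) {
      # trim the freshly added pixels, dropping those farthest from the
      # blob center so the kept part stays a coherent (smaller) blob
      ri <- (new_idx - 1L) %% H + 1L
      ci <- (new_idx - 1L) %/% H + 1L
      d2 <- (ri - center[1])^2 + (ci - center[2])^2
      keep <- new_idx[order(d2)][seq_len(length(new_idx) - overshoot)]
      new_idx <- keep
    }
    mask[new_idx] <- 1L
    count <- count + length(new_idx)
  }
  mask
}

# Paint the background: hematoxylin wash + nucleus ellipses + eosin patches.
render_background <- function(H, W, palette, jitter = 8L) {
  img <- array(0, dim = c(H, W, 3L))
  for (ch in 1:3) {
    img[, , ch] <- palette$background[ch] +
      sample(seq(-jitter, jitter), H * W, replace = TRUE)
  }
  paint <- function(img, idx, color, jit) {
    if (!length(idx)) return(img)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[idx] <- color[ch] + sample(seq(-jit, jit), length(idx), TRUE)
      img[, , ch] <- plane
    }
    img
  }
  # eosin patches: a few large soft ellipses
  n_eosin <- max(1L, round(H * W / 60000))
  for (i in seq_len(n_eosin)) {
    idx <- ellipse_pixels(
      c(runif(1, 1, H), runif(1, 1, W)),
      runif(2, H / 10, H / 4), runif(1, 0, pi), H, W
    )
    img <- paint(img, idx, palette$eosin, 8L)
  }
  # hematoxylin-dark nuclei scattered over the field
  n_nuc <- max(1L, round(H * W / 2500))
  for (i in seq_len(n_nuc)) {
    idx <- ellipse_pixels(
      c(runif(1, 1, H), runif(1, 1, W)),
      runif(2, 2, 5), runif(1, 0, pi), H, W
    )
    img <- paint(img, idx, palette$nucleus, 6L)
  }
  img
}

#' Generate a synthetic IHC field with exact ground truth
#'
#' Renders an IHC-like RGB image of DAB-stained cell blobs over a
#' hematoxylin-style background, together with the binary ground-truth
#' stain mask. The stained pixel count is adjusted exactly, so
#' `true_fraction` matches `target_fraction` to pixel granularity (well
#' within 0.5 percentage points at the default extent). The returned field
#' is in the clean `GOOD` regime: by palette construction it contains no
#' brown-family pixels outside the truth mask.
#'
#' @param params a [field_gen_params()] object (or arguments passed on to
#'   it via `...`).
#' @param field_id identifier string stored on the field.
#' @param marker CD marker label stored on the field (provenance only; the
#'   renderer does not model marker-specific morphology).
#' @param ... used to build `params` when it is not supplied.
#' @return An object of class `synthetic_field`: a list with `image`
#'   (H x W x 3 integer array, 0-255), `mask` (H x W integer matrix, 1 =
#'   stained), `true_fraction` (percent), `regime` (`"GOOD"`), `field_id`,
#'   `marker`, `stain_color`, and `params`.
#' @examples
#' f <- generate_field(field_gen_params(extent = c(64, 64),
#'                                      target_fraction = 10, seed = 1))
#' f$true_fraction
#' @export
generate_field <- function(params = field_gen_params(...), field_id = "F0001",
                           marker = "CD3", ...) {
  stopifnot(inherits(params, "field_gen_params"))
  H <- params$extent[1]; W <- params$extent[2]
  total <- H * W
  n_target <- round(params$target_fraction / 100 * total)
  with_seed(params$seed, {
    mask <- build_blob_mask(H, W, n_target, params$blob_axes)
    img <- render_background(H, W, params$background_palette)
    idx <- which(mask == 1L)
    if (length(idx)) {
      jit <- params$stain_jitter
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[idx] <- params$stain_color[ch] +
          sample(seq(-jit, jit), length(idx), replace = TRUE)
        img[, , ch] <- plane
      }
    }
    img <- clip(round(img), 0, 255)
    storage.mode(img) <- "integer"
    structure(
      list(
        image = img,
        mask = mask,
        true_fraction = 100 * sum(mask) / total,
        regime = "GOOD",
        field_id = field_id,
        marker = match.arg(marker, IHC_MARKERS),
        stain_color = params$stain_color,
        params = params
      ),
      class = "synthetic_field"
    )
  })
}

#' @export
print.synthetic_field <- function(x, ...) {
  cat(sprintf(
    "<synthetic_field %s> %dx%d px, regime %s, marker %s, true fraction %.3f%%\n",
    x$field_id, nrow(x$mask), ncol(x$mask), x$regime, x$marker,
    x$true_fraction
  ))
  invisible(x)
}

#' Add diffuse non-specific brown background to a field
#'
#' Converts a clean `GOOD` field into its paired `NOISE` regime by blending
#' a smooth brown haze (sum of random Gaussian bumps) plus small brown
#' speckles into the *background* pixels only. The truth mask and
#' `true_fraction` are untouched: noise never alters ground truth, it only
#' makes non-stained pixels resemble the stain.
#'
#' @param field a `GOOD` [generate_field()] result.
#' @param noise_intensity scalar in \[0, 1\] scaling haze coverage and
#'   opacity; 0 returns the image unchanged (regime still flagged NOISE).
#' @param seed integer seed for the haze pattern.
#' @return The field with `regime = "NOISE"` and a contaminated image.
#' @export
add_background_noise <- function(field, noise_intensity = 0.5, seed = 1L) {
  stopifnot(inherits(field, "synthetic_field"))
  if (field$regime != "GOOD") stop("field must be in the GOOD regime")
  if (!is.numeric(noise_intensity) || length(noise_intensity) != 1L ||
      noise_intensity < 0 || noise_intensity > 1) {
    stop("noise_intensity must be a scalar in [0, 1]")
  }
  out <- field
  out$regime <- "NOISE"
  if (noise_intensity == 0) return(out)
  H <- nrow(field$mask); W <- ncol(field$mask)
  with_seed(seed, {
    w <- matrix(0, H, W)
    n_bumps <- max(1L, round(40 * noise_intensity))
    for (i in seq_len(n_bumps)) {
      r0 <- runif(1, 1, H); c0 <- runif(1, 1, W)
      sigma <- runif(1, H / 25, H / 8)
      amp <- runif(1, 0.35, 0.9) * noise_intensity
      ext <- ceiling(3 * sigma)
      rows <- max(1L, floor(r0 - ext)):min(H, ceiling(r0 + ext))
      cols <- max(1L, floor(c0 - ext)):min(W, ceiling(c0 + ext))
      g <- amp * exp(-outer((rows - r0)^2, (cols - c0)^2, "+") / (2 * sigma^2))
      w[rows, cols] <- w[rows, cols] + g
    }
    w <- pmin(w, 0.95)
    # small dark speckles of near-stain color
    n_spk <- round(H * W * 0.003 * noise_intensity)
    if (n_spk > 0) {
      spk <- sample.int(H * W, n_spk)
      w[spk] <- runif(n_spk, 0.75, 1)
    }
    w[field$mask == 1L] <- 0  # never touch ground-truth pixels
    img <- out$image
    jit <- sample(seq(-12L, 12L), H * W, replace = TRUE)
    for (ch in 1:3) {
      plane <- img[, , ch]
      brown <- field$stain_color[ch] + jit
      plane <- (1 - w) * plane + w * brown
      img[, , ch] <- plane
    }
    img <- clip(round(img), 0, 255)
    storage.mode(img) <- "integer"
    out$image <- img
  })
  out
}

#' Generate the GOOD/NOISE picture set of an agreement study
#'
#' Produces `n_good` clean fields and `n_noise` noisy-background fields
#' (each NOISE field is a clean field passed through
#' [add_background_noise()]), with true stained fractions drawn uniformly
#' from `fraction_range` — by default 1-30%, the sparse range typical of
#' inflammatory-marker staining — and markers cycling through the seven
#' CD markers. Deterministic under `seed`.
#'
#' @param n_good,n_noise numbers of clean / noisy fields (>= 0).
#' @param seed master seed.
#' @param extent pixel extent passed to the generator.
#' @param fraction_range range of true stained fractions, percent.
#' @param noise_intensity haze intensity for the NOISE fields.
#' @return A list of `synthetic_field` objects (GOOD first, then NOISE).
#' @export
generate_study_fixtures <- function(n_good, n_noise, seed = 1L,
                                    extent = c(512L, 512L),
                                    fraction_range = c(1, 30),
                                    noise_intensity = 0.5) {
  stopifnot(is_count(n_good), is_count(n_noise))
  n <- n_good + n_noise
  if (n == 0L) return(list())
  seeds <- derive_seeds(seed, 2L * n)
  fracs <- with_seed(seed + 1L,
                     runif(n, fraction_range[1], fraction_range[2]))
  markers <- rep_len(IHC_MARKERS, n)
  fields <- vector("list", n)
  for (i in seq_len(n)) {
    regime <- if (i <= n_good) "GOOD" else "NOISE"
    f <- generate_field(
      field_gen_params(extent = extent, target_fraction = fracs[i],
                       seed = seeds[i]),
      field_id = sprintf("%s%04d", substr(regime, 1, 1), i),
      marker = markers[i]
    )
    if (regime == "NOISE") {
      f <- add_background_noise(f, noise_intensity, seed = seeds[n + i])
    }
    fields[[i]] <- f
  }
  fields
}

#' Write synthetic fields to disk
#'
#' Writes each field as `<id>_img.png` (RGB) and `<id>_mask.png` (binary),
#' plus a `manifest.csv` with columns `field_id`, `regime`, `marker`,
#' `true_fraction`, `seed`.
#'
#' @param fields list of `synthetic_field` objects.
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest data frame.
#' @export
write_fields <- function(fields, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(
    field_id = vapply(fields, `[[`, "", "field_id"),
    regime = vapply(fields, `[[`, "", "regime"),
    marker = vapply(fields, `[[`, "", "marker"),
    true_fraction = vapply(fields, `[[`, 0, "true_fraction"),
    seed = vapply(fields, function(f) f$params$seed, 0L)
  )
  for (f in fields) {
    png::writePNG(f$image / 255,
                  file.path(dir, paste0(f$field_id, "_img.png")))
    png::writePNG(f$mask + 0, file.path(dir, paste0(f$field_id, "_mask.png")))
  }
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read an RGB image into the package's 8-bit array convention
#'
#' @param path a PNG file.
#' @return An H x W x 3 integer array with values 0-255.
#' @export
read_ihc_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  img <- img[, , 1:3, drop = FALSE]
  img <- round(img * 255)
  storage.mode(img) <- "integer"
  img
}
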