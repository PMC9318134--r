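# Color-range pixel selection: select every pixel within a fuzziness
# tolerance of one or more sampled stain colors; the selected/total pixel
# ratio is the stained-area percentage.

#' Specify a color-range selection rule
#'
#' A pixel is selected when its distance to the *nearest* sampled color is
#' within the fuzziness tolerance (multiple sampled colors combine by
#' union). Under the default `"hard"` falloff the selection is binary, as
#' implied by counting pixels off a histogram; `"linear"` falloff instead
#' gives each pixel a weight of 1 up to fuzziness/2, decaying linearly to 0
#' at the full fuzziness — a graded-selection mode for sensitivity
#' analysis.
#'
#' @param sampled_colors an RGB triple or a matrix with one RGB triple per
#'   row (8-bit values).
#' @param fuzziness integer tolerance in \[0, 255\]; default 100.
#' @param metric `"chebyshev"` (max per-channel difference; default, the
#'   closest published analogue of per-channel fuzziness semantics) or
#'   `"euclidean"`.
#' @param falloff `"hard"` (binary) or `"linear"` (graded weights).
#' @return An object of class `color_range_spec`.
#' @export
color_range_spec <- function(sampled_colors = DEFAULT_STAIN_COLOR,
                             fuzziness = 100L,
                             metric = c("chebyshev", "euclidean"),
                             falloff = c("hard", "linear")) {
  if (is.null(dim(sampled_colors))) {
    sampled_colors <- matrix(sampled_colors, nrow = 1L)
  }
  sampled_colors <- as.matrix(sampled_colors)
  if (nrow(sampled_colors) < 1L || ncol(sampled_colors) != 3L) {
    stop("sampled_colors must hold at least one RGB triple")
  }
  if (!is.numeric(fuzziness) || length(fuzziness) != 1L ||
      fuzziness < 0 || fuzziness > 255) {
    stop("fuzziness must be a scalar in [0, 255]")
  }
  structure(
    list(sampled_colors = unname(sampled_colors),
         fuzziness = as.numeric(fuzziness),
         metric = match.arg(metric),
         falloff = match.arg(falloff)),
    class = "color_range_spec"
  )
}

#' Sample a reference stain color from an image
#'
#' Emulates picking a stained cell with an eyedropper: returns the RGB
#' value at the given pixel, or (with `median3 = TRUE`) the per-channel
#' median over the 3 x 3 neighborhood clamped at the borders.
#'
#' @param image RGB array or `synthetic_field`.
#' @param at numeric `c(row, col)`, continuous 0-based coordinates inside
#'   the extent.
#' @param median3 use the 3 x 3 median variant.
#' @return Integer RGB triple.
#' @export
sample_stain_color <- function(image, at, median3 = FALSE) {
  img <- as_ihc_image(image)
  H <- dim(img)[1]; W <- dim(img)[2]
  if (at[1] < 0 || at[1] >= H || at[2] < 0 || at[2] >= W) {
    stop("sampling coordinate outside the image extent")
  }
  ri <- point_to_pixel(at[1], H)
  ci <- point_to_pixel(at[2], W)
  if (!median3) return(as.integer(img[ri, ci, ]))
  rows <- clip((ri - 1L):(ri + 1L), 1L, H)
  cols <- clip((ci - 1L):(ci + 1L), 1L, W)
  as.integer(round(apply(img[rows, cols, , drop = FALSE], 3, median)))
}

#' Select pixels within a color range
#'
#' @param image RGB array or `synthetic_field`.
#' @param spec a [color_range_spec()].
#' @return An object of class `selection_mask`: a list with `weights`
#'   (H x W matrix in \[0, 1\]; 0/1 under hard falloff), `selected_count`
#'   (sum of weights), `total_count`, and the `spec`.
#' @export
color_range_select <- function(image, spec = color_range_spec()) {
  stopifnot(inherits(spec, "color_range_spec"))
  img <- as_ihc_image(image)
  H <- dim(img)[1]; W <- dim(img)[2]
  d <- NULL
  for (k in seq_len(nrow(spec$sampled_colors))) {
    ref <- spec$sampled_colors[k, ]
    dk <- color_distance(img[, , 1] - ref[1], img[, , 2] - ref[2],
                         img[, , 3] - ref[3], spec$metric)
    d <- if (is.null(d)) dk else pmin(d, dk)
  }
  f <- spec$fuzziness
  if (spec$falloff == "hard") {
    w <- (d <= f) * 1
  } else if (f == 0) {
    w <- (d == 0) * 1
  } else {
    w <- clip(1 - (d - f / 2) / (f / 2), 0, 1)
  }
  structure(
    list(weights = w, selected_count = sum(w), total_count = H * W,
         spec = spec),
    class = "selection_mask"
  )
}

#' Color-range estimate of the stained-area fraction
#'
#' `100 * selected_count / total_count` for the given selection rule.
#'
#' @inheritParams color_range_select
#' @return A numeric percentage in \[0, 100\] with attributes
#'   `selected_count` and `total_count`.
#' @export
dc_area_fraction <- function(image, spec = color_range_spec()) {
  sel <- color_range_select(image, spec)
  structure(100 * sel$selected_count / sel$total_count,
            selected_count = sel$selected_count,
            total_count = sel$total_count)
}

#' Save / load a color-range selection rule
#'
#' The selection criterion is meant to be defined once and reapplied to
#' every image of a series; these helpers serialize it to a small YAML or
#' JSON file (by extension).
#'
#' @param spec a [color_range_spec()].
#' @param path file ending in `.yaml`, `.yml`, or `.json`.
#' @return `write_color_range_spec` returns `path` invisibly;
#'   `read_color_range_spec` returns the restored `color_range_spec`.
#' @export
write_color_range_spec <- function(spec, path) {
  stopifnot(inherits(spec, "color_range_spec"))
  obj <- list(
    sampled_colors = apply(spec$sampled_colors, 1, as.integer,
                           simplify = FALSE),
    fuzziness = spec$fuzziness,
    metric = spec$metric,
    falloff = spec$falloff
  )
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_color_range_spec
#' @param path file to read.
#' @export
read_color_range_spec <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  sc <- obj$sampled_colors
  colors <- if (is.matrix(sc)) sc else do.call(rbind, lapply(sc, as.numeric))
  color_range_spec(colors, obj$fuzziness, obj$metric, obj$falloff)
}
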