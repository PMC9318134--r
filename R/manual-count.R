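# Point-counting (stereological) estimation of the stained-area fraction:
# a sampling grid is superimposed on the image and the share of points that
# hit stained tissue estimates the area percentage.

#' Specify a point-counting grid
#'
#' The default 27 x 22 layout gives the classical 594-point counting grid
#' (594 = 27 x 22, approximating a 4:3 field).
#'
#' @param n_rows,n_cols grid dimensions; their product is the number of
#'   sampling points.
#' @param placement `"systematic_offset"` places point (i, j) at the center
#'   of grid cell (i, j) — half-cell margins, no points on the border;
#'   `"uniform_random"` draws all points i.i.d. uniformly over the raster.
#' @param seed integer seed, used only for `"uniform_random"`.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows = 27L, n_cols = 22L,
                      placement = c("systematic_offset", "uniform_random"),
                      seed = 1L) {
  placement <- match.arg(placement)
  if (!is_count(n_rows) || !is_count(n_cols) || n_rows < 1 || n_cols < 1) {
    stop("n_rows and n_cols must be positive integers")
  }
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         placement = placement, seed = as.integer(seed)),
    class = "grid_spec"
  )
}

#' Build the sampling points of a grid over an image extent
#'
#' Coordinates are continuous `(row, col)` pairs, 0-based, origin at the
#' top-left pixel corner. Systematic placement puts point (i, j) at
#' `((i + 0.5) * H / n_rows, (j + 0.5) * W / n_cols)`.
#'
#' @param spec a [grid_spec()].
#' @param extent integer `c(height, width)` in pixels; must be at least as
#'   large as the grid dimensions.
#' @return An object of class `point_grid`: a data frame with columns
#'   `row`, `col` and attributes `extent` and `spec`.
#' @examples
#' g <- build_grid(grid_spec(2, 2), c(100, 100))
#' g  # points at (25,25), (25,75), (75,25), (75,75)
#' @export
build_grid <- function(spec, extent) {
  stopifnot(inherits(spec, "grid_spec"), length(extent) == 2L)
  H <- extent[1]; W <- extent[2]
  if (H < spec$n_rows || W < spec$n_cols) {
    stop("extent must be at least as large as the grid dimensions")
  }
  n <- spec$n_rows * spec$n_cols
  if (spec$placement == "systematic_offset") {
    r <- (seq_len(spec$n_rows) - 0.5) * H / spec$n_rows
    c <- (seq_len(spec$n_cols) - 0.5) * W / spec$n_cols
    pts <- expand.grid(row = r, col = c, KEEP.OUT.ATTRS = FALSE)
  } else {
    pts <- with_seed(spec$seed, data.frame(
      row = runif(n, 0, H), col = runif(n, 0, W)
    ))
  }
  structure(pts, extent = as.integer(extent), spec = spec,
            class = c("point_grid", "data.frame"))
}

#' Define how a grid point is judged "stained"
#'
#' Two surrogates for the human decision of whether an intersection point
#' falls on brown-stained cytoplasm or membrane:
#' `"oracle_mask"` reads the ground-truth mask (ideal observer, useful for
#' estimator-property checks); `"color_rule"` compares the pixel color to a
#' reference brown within a tolerance, so an imperfect observer can be
#' emulated by perturbing the reference color or tolerance.
#'
#' @param mode `"oracle_mask"` or `"color_rule"`.
#' @param reference_color RGB triple for `"color_rule"`.
#' @param tolerance max color distance counted as a hit.
#' @param metric `"chebyshev"` (max per-channel difference) or
#'   `"euclidean"`.
#' @return An object of class `hit_classifier`.
#' @export
hit_classifier <- function(mode = c("oracle_mask", "color_rule"),
                           reference_color = DEFAULT_STAIN_COLOR,
                           tolerance = 100,
                           metric = c("chebyshev", "euclidean")) {
  structure(
    list(mode = match.arg(mode),
         reference_color = as.numeric(reference_color),
         tolerance = as.numeric(tolerance),
         metric = match.arg(metric)),
    class = "hit_classifier"
  )
}

color_distance <- function(dr, dg, db, metric) {
  if (metric == "chebyshev") {
    pmax(abs(dr), abs(dg), abs(db))
  } else {
    sqrt(dr^2 + dg^2 + db^2)
  }
}

#' Classify grid points as stained or not
#'
#' Each continuous point is mapped to the pixel containing it (pixel i
#' spans `[i, i+1)`; a coordinate exactly on an integer pixel boundary
#' resolves down to the lower pixel) and judged by the classifier. Points
#' outside the image extent are an error.
#'
#' @param x a `synthetic_field`, or an RGB image array (`color_rule`), or a
#'   binary mask matrix (`oracle_mask`).
#' @param grid a [build_grid()] result (or a data frame with `row`, `col`).
#' @param classifier a [hit_classifier()].
#' @return Logical vector, one entry per grid point.
#' @export
classify_points <- function(x, grid, classifier = hit_classifier()) {
  stopifnot(inherits(classifier, "hit_classifier"))
  if (classifier$mode == "oracle_mask") {
    mask <- if (inherits(x, "synthetic_field")) x$mask else x
    if (!is.matrix(mask)) stop("oracle_mask mode needs a binary mask matrix")
    H <- nrow(mask); W <- ncol(mask)
    check_points_inside(grid, H, W)
    ri <- point_to_pixel(grid$row, H)
    ci <- point_to_pixel(grid$col, W)
    mask[cbind(ri, ci)] == 1L
  } else {
    img <- as_ihc_image(x)
    H <- dim(img)[1]; W <- dim(img)[2]
    check_points_inside(grid, H, W)
    ri <- point_to_pixel(grid$row, H)
    ci <- point_to_pixel(grid$col, W)
    px <- cbind(img[, , 1][cbind(ri, ci)],
                img[, , 2][cbind(ri, ci)],
                img[, , 3][cbind(ri, ci)])
    ref <- classifier$reference_color
    d <- color_distance(px[, 1] - ref[1], px[, 2] - ref[2], px[, 3] - ref[3],
                        classifier$metric)
    d <= classifier$tolerance
  }
}

check_points_inside <- function(grid, H, W) {
  if (any(grid$row < 0 | grid$row >= H | grid$col < 0 | grid$col >= W)) {
    stop("grid contains points outside the image extent")
  }
  invisible(TRUE)
}

#' Classify a single point
#'
#' @inheritParams classify_points
#' @param point numeric `c(row, col)`, continuous 0-based coordinates.
#' @return `TRUE` if the point falls on stained tissue.
#' @export
classify_point <- function(x, point, classifier = hit_classifier()) {
  classify_points(x, data.frame(row = point[1], col = point[2]), classifier)
}

#' Point-counting estimate of the stained-area fraction
#'
#' Returns `100 * hits / n_points`: the percentage of grid points that fall
#' on stained tissue. With the default 594-point grid the estimate has a
#' granularity of 100/594 ~ 0.17 percentage points.
#'
#' @inheritParams classify_points
#' @return A numeric percentage in \[0, 100\] with attributes `hits` and
#'   `n_points`.
#' @export
mc_area_fraction <- function(x, grid, classifier = hit_classifier()) {
  if (nrow(grid) == 0L) stop("grid is empty")
  hits <- classify_points(x, grid, classifier)
  structure(100 * sum(hits) / length(hits),
            hits = sum(hits), n_points = length(hits))
}
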