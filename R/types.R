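#' Categorical label raster
#'
#' A per-pixel class grid with physical calibration. Pixels use 0-based
#' (x, y) indices with the origin at the top-left corner; the micron
#' position of pixel (x, y) is its top-left corner at
#' `origin_um + c(x, y) * mpp`, so rasters at the three working resolutions
#' (4, 0.5 and 0.25 microns per pixel) share one micron frame and can be
#' looked up across resolutions.
#'
#' @param grid Integer matrix of class indices (1-based into `classes`),
#'   stored as `grid[y + 1, x + 1]`.
#' @param classes Character vector naming the declared classes.
#' @param mpp Microns per pixel (positive).
#' @param origin_um Numeric length-2, micron offset of pixel (0, 0).
#' @return A `label_raster` object.
#' @export
label_raster <- function(grid, classes, mpp, origin_um = c(0, 0)) {
  stopifnot_scalar_number(mpp, "mpp", positive = TRUE)
  if (!is.matrix(grid)) itil_error("itil_invalid_argument", "`grid` must be a matrix")
  grid <- matrix(as.integer(grid), nrow(grid), ncol(grid))
  if (anyNA(grid) || any(grid < 1L) || any(grid > length(classes))) {
    itil_error("itil_invalid_argument", "every pixel must hold a declared class")
  }
  structure(
    list(grid = grid, classes = as.character(classes), mpp = mpp,
         origin_um = as.numeric(origin_um)),
    class = "label_raster"
  )
}

# fast internal constructor: callers guarantee the grid is a valid integer
# matrix of class indices (skips the full-grid validation scan)
new_label_raster <- function(grid, classes, mpp, origin_um = c(0, 0)) {
  structure(list(grid = grid, classes = as.character(classes), mpp = mpp,
                 origin_um = as.numeric(origin_um)),
            class = "label_raster")
}

#' @export
print.label_raster <- function(x, ...) {
  cat(sprintf("<label_raster> %d x %d px @ %g MPP, origin (%g, %g) um\n",
              ncol(x$grid), nrow(x$grid), x$mpp, x$origin_um[1], x$origin_um[2]))
  tab <- table(factor(x$classes[x$grid], levels = x$classes))
  for (cl in names(tab)) {
    cat(sprintf("  %-10s %d px (%.4f mm^2)\n", cl, tab[[cl]],
                tab[[cl]] * (x$mpp / 1000)^2))
  }
  invisible(x)
}

# (width, height) in pixels
raster_extent_px <- function(r) c(ncol(r$grid), nrow(r$grid))

# (width, height) in microns
raster_extent_um <- function(r) raster_extent_px(r) * r$mpp

raster_class_id <- function(r, cls) {
  id <- match(cls, r$classes)
  if (is.na(id)) {
    itil_error("itil_invalid_argument",
               sprintf("class '%s' is not declared in this raster", cls))
  }
  id
}

#' Look up raster classes at micron coordinates
#'
#' Nearest-neighbour lookup in the shared micron frame: each coordinate is
#' mapped to the pixel containing it. Coordinates outside the raster return
#' `NA`.
#'
#' @param r A [label_raster()].
#' @param x_um,y_um Numeric vectors of micron coordinates.
#' @return Character vector of class names (`NA` outside the extent).
#' @export
raster_class_at <- function(r, x_um, y_um) {
  px <- floor((x_um - r$origin_um[1]) / r$mpp)
  py <- floor((y_um - r$origin_um[2]) / r$mpp)
  ext <- raster_extent_px(r)
  ok <- px >= 0 & px < ext[1] & py >= 0 & py < ext[2]
  out <- rep(NA_character_, length(x_um))
  if (any(ok)) {
    idx <- cbind(py[ok] + 1L, px[ok] + 1L)
    out[ok] <- r$classes[r$grid[idx]]
  }
  out
}

#' Point set in micron coordinates
#'
#' Detections or annotations as (x, y) micron coordinates with a per-point
#' confidence in [0, 1] and an optional tissue-compartment label.
#'
#' @param x_um,y_um Numeric coordinates in microns.
#' @param confidence Numeric in [0, 1] (recycled).
#' @param compartment Character labels (recycled), e.g. "tumour", "stroma",
#'   "necrosis" or "unassigned".
#' @return A data frame of class `point_set` with columns `x_um`, `y_um`,
#'   `confidence`, `compartment`.
#' @export
point_set <- function(x_um = numeric(), y_um = numeric(),
                      confidence = rep(1, length(x_um)),
                      compartment = rep(NA_character_, length(x_um))) {
  n <- length(x_um)
  if (length(y_um) != n) itil_error("itil_invalid_argument", "x_um and y_um lengths differ")
  confidence <- rep_len(as.numeric(confidence), n)
  if (n > 0 && (anyNA(confidence) || any(confidence < 0 | confidence > 1))) {
    itil_error("itil_invalid_argument", "confidence must lie in [0, 1]")
  }
  df <- data.frame(x_um = as.numeric(x_um), y_um = as.numeric(y_um),
                   confidence = confidence,
                   compartment = rep_len(as.character(compartment), n),
                   stringsAsFactors = FALSE)
  class(df) <- c("point_set", "data.frame")
  df
}

as_point_set <- function(df) {
  point_set(df$x_um, df$y_um,
            confidence = if (is.null(df$confidence)) rep(1, nrow(df)) else df$confidence,
            compartment = if (is.null(df$compartment)) rep(NA_character_, nrow(df)) else df$compartment)
}

#' RGB raster with physical calibration
#'
#' An in-memory 8-bit RGB image (values 0-255) sharing the micron-frame
#' conventions of [label_raster()]. Whole slides are usually better
#' represented lazily via [slide_source()]; this container suits tiles and
#' small fixtures.
#'
#' @param rgb Numeric array `h x w x 3` with values in [0, 255].
#' @param mpp Microns per pixel.
#' @param origin_um Micron offset of pixel (0, 0).
#' @return An `rgb_raster` object.
#' @export
rgb_raster <- function(rgb, mpp, origin_um = c(0, 0)) {
  stopifnot_scalar_number(mpp, "mpp", positive = TRUE)
  if (!is.array(rgb) || length(dim(rgb)) != 3L || dim(rgb)[3] != 3L) {
    itil_error("itil_invalid_argument", "`rgb` must be an h x w x 3 array")
  }
  structure(list(rgb = rgb, mpp = mpp, origin_um = as.numeric(origin_um)),
            class = "rgb_raster")
}
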