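#' Plan a tile grid over a slide extent
#'
#' Lays 512 x 512 px (by default) tiles over a pixel extent at a given
#' resolution, with optional overlap between neighbouring tiles. Edge tiles
#' are clipped to the extent, never padded, so the union of tiles covers the
#' extent exactly; with zero overlap tiles are disjoint. Tiles are ordered
#' row-major (left to right, then top to bottom), which is also the
#' "last-writer-wins" order used by [reconstruct_raster()].
#'
#' @param extent_px Integer length-2 `(width, height)` in pixels.
#' @param tile_size_px Tile side in pixels (default 512).
#' @param overlap_px Overlap between adjacent tiles, `0 <= overlap < size`.
#' @param mpp Microns per pixel, used to derive micron bounds.
#' @param origin_um Micron offset of pixel (0, 0).
#' @return A `tile_plan`: list with `tiles` (data frame of half-open pixel
#'   bounds `px0, py0, px1, py1` and micron bounds `ux0, uy0, ux1, uy1`),
#'   plus the planning parameters.
#' @examples
#' plan_tiles(c(1024, 1024), 512, 0, mpp = 4)$tiles
#' @export
plan_tiles <- function(extent_px, tile_size_px = 512L, overlap_px = 0L, mpp = 1,
                       origin_um = c(0, 0)) {
  extent_px <- as.integer(extent_px)
  if (length(extent_px) != 2L || any(extent_px <= 0L)) {
    itil_error("itil_invalid_argument", "extent_px must be two positive integers")
  }
  tile_size_px <- as.integer(tile_size_px)
  overlap_px <- as.integer(overlap_px)
  if (tile_size_px <= 0L) itil_error("itil_invalid_argument", "tile_size_px must be positive")
  if (overlap_px < 0L || overlap_px >= tile_size_px) {
    itil_error("itil_invalid_argument", "overlap_px must satisfy 0 <= overlap < tile size")
  }
  stopifnot_scalar_number(mpp, "mpp", positive = TRUE)

  stride <- tile_size_px - overlap_px
  starts_1d <- function(extent) {
    s <- seq.int(0L, max(0L, extent - 1L), by = stride)
    ends <- pmin(s + tile_size_px, extent)
    # drop a trailing clipped tile adding no new coverage
    keep <- c(TRUE, ends[-1] > ends[-length(ends)])
    s[keep]
  }
  xs <- starts_1d(extent_px[1])
  ys <- starts_1d(extent_px[2])

  g <- expand.grid(px0 = xs, py0 = ys)              # x fastest -> row-major
  tiles <- data.frame(
    index = seq_len(nrow(g)),
    px0 = g$px0, py0 = g$py0,
    px1 = pmin(g$px0 + tile_size_px, extent_px[1]),
    py1 = pmin(g$py0 + tile_size_px, extent_px[2])
  )
  tiles$ux0 <- origin_um[1] + tiles$px0 * mpp
  tiles$uy0 <- origin_um[2] + tiles$py0 * mpp
  tiles$ux1 <- origin_um[1] + tiles$px1 * mpp
  tiles$uy1 <- origin_um[2] + tiles$py1 * mpp

  structure(list(tiles = tiles, extent_px = extent_px,
                 tile_size_px = tile_size_px, overlap_px = overlap_px,
                 mpp = mpp, origin_um = as.numeric(origin_um)),
            class = "tile_plan")
}

#' @export
print.tile_plan <- function(x, ...) {
  cat(sprintf("<tile_plan> %d tiles of %d px (overlap %d) over %d x %d px @ %g MPP\n",
              nrow(x$tiles), x$tile_size_px, x$overlap_px,
              x$extent_px[1], x$extent_px[2], x$mpp))
  invisible(x)
}

#' Split a label raster into per-tile grids
#'
#' Inverse companion of [reconstruct_raster()]; used for round-trip testing
#' and for feeding per-tile consumers.
#'
#' @param raster A [label_raster()].
#' @param plan A [plan_tiles()] plan matching the raster extent.
#' @return List of integer matrices, one per tile in plan order.
#' @export
split_raster <- function(raster, plan) {
  lapply(seq_len(nrow(plan$tiles)), function(i) {
    t <- plan$tiles[i, ]
    raster$grid[(t$py0 + 1):t$py1, (t$px0 + 1):t$px1, drop = FALSE]
  })
}

#' Reconstruct a slide-level raster from per-tile predictions
#'
#' Writes per-tile class grids back into a single slide raster. Where tiles
#' overlap, the later tile in row-major plan order wins ("last-writer-wins");
#' with zero overlap the reconstruction is an exact inverse of
#' [split_raster()].
#'
#' @param per_tile_predictions List of integer class-index matrices, one per
#'   tile in plan order, each matching its tile's (possibly clipped) shape.
#' @param plan The [plan_tiles()] plan the predictions were made under.
#' @param classes Character vector naming the predicted classes.
#' @return A [label_raster()] covering the planned extent.
#' @export
reconstruct_raster <- function(per_tile_predictions, plan, classes) {
  nt <- nrow(plan$tiles)
  if (length(per_tile_predictions) != nt) {
    itil_error("itil_incomplete_input",
               sprintf("expected %d tile predictions, got %d",
                       nt, length(per_tile_predictions)))
  }
  grid <- matrix(NA_integer_, plan$extent_px[2], plan$extent_px[1])
  for (i in seq_len(nt)) {
    t <- plan$tiles[i, ]
    pred <- per_tile_predictions[[i]]
    if (is.null(pred)) {
      itil_error("itil_incomplete_input", sprintf("missing prediction for tile %d", i))
    }
    if (nrow(pred) != t$py1 - t$py0 || ncol(pred) != t$px1 - t$px0) {
      itil_error("itil_invalid_argument",
                 sprintf("tile %d prediction shape %dx%d does not match tile %dx%d",
                         i, nrow(pred), ncol(pred), t$py1 - t$py0, t$px1 - t$px0))
    }
    grid[(t$py0 + 1):t$py1, (t$px0 + 1):t$px1] <- pred
  }
  if (anyNA(grid)) {
    itil_error("itil_incomplete_input", "tile plan does not cover the extent")
  }
  new_label_raster(grid, classes, plan$mpp, plan$origin_um)
}

#' Area of a raster class in square millimetres
#'
#' `count(class pixels) * (mpp / 1000)^2`; the quantity that normalises the
#' per-field iTIL counts (tumour area in mm^2).
#'
#' @param raster A [label_raster()].
#' @param cls A declared class name.
#' @return Area in mm^2 (nonnegative).
#' @export
class_area_mm2 <- function(raster, cls) {
  id <- raster_class_id(raster, cls)
  sum(raster$grid == id) * (raster$mpp / 1000)^2
}

#' Resample a label raster to a different resolution
#'
#' Nearest-neighbour resampling in the shared micron frame, preserving label
#' semantics (no interpolated classes). The output covers the same micron
#' extent.
#'
#' @param raster A [label_raster()].
#' @param target_mpp Output microns per pixel.
#' @return A [label_raster()] at `target_mpp`.
#' @export
resample_label <- function(raster, target_mpp) {
  stopifnot_scalar_number(target_mpp, "target_mpp", positive = TRUE)
  ext_um <- raster_extent_um(raster)
  out_w <- max(1L, as.integer(round(ext_um[1] / target_mpp)))
  out_h <- max(1L, as.integer(round(ext_um[2] / target_mpp)))
  # source pixel containing each output pixel centre
  sx <- pmin(ncol(raster$grid) - 1L,
             pmax(0L, floor(((seq_len(out_w) - 0.5) * target_mpp) / raster$mpp)))
  sy <- pmin(nrow(raster$grid) - 1L,
             pmax(0L, floor(((seq_len(out_h) - 0.5) * target_mpp) / raster$mpp)))
  new_label_raster(raster$grid[sy + 1L, sx + 1L, drop = FALSE], raster$classes,
                   target_mpp, raster$origin_um)
}

#' Downsample an RGB array by an integer factor
#'
#' Area-weighted (block-mean) downsampling, the anti-aliased choice for
#' photographic content; labels go through [resample_label()] instead.
#'
#' @param rgb Numeric `h x w x 3` array.
#' @param factor Positive integer downsampling factor; the input extent must
#'   be divisible by it.
#' @return Downsampled `h/f x w/f x 3` array.
#' @export
downsample_rgb <- function(rgb, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) itil_error("itil_invalid_argument", "factor must be >= 1")
  if (factor == 1L) return(rgb)
  d <- dim(rgb)
  if (d[1] %% factor != 0L || d[2] %% factor != 0L) {
    itil_error("itil_invalid_argument", "extent not divisible by downsampling factor")
  }
  h <- d[1] %/% factor; w <- d[2] %/% factor
  out <- array(0, c(h, w, 3))
  for (ch in 1:3) {
    m <- rgb[, , ch]
    # average factor x factor blocks
    m <- matrix(colMeans(matrix(m, factor)), h, d[2])         # rows
    m <- t(matrix(colMeans(matrix(t(m), factor)), w, h))      # cols
    out[, , ch] <- m
  }
  out
}
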