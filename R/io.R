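# File interchange: label rasters as single-channel PNG with a sidecar
# JSON ({mpp, origin_um, class_map}), points as CSV or QuPath-compatible
# GeoJSON, heatmaps as float TIFF, configuration as YAML.

sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a label raster as PNG + sidecar JSON
#'
#' The PNG stores the 0-based class index per pixel (index/255 grey); the
#' sidecar JSON carries the physical calibration and class map.
#'
#' @param raster A [label_raster()].
#' @param path Output PNG path (the sidecar goes to `<path>.json`).
#' @return `write_label_raster()` returns `path` invisibly;
#'   `read_label_raster()` returns a [label_raster()].
#' @export
write_label_raster <- function(raster, path) {
  if (length(raster$classes) > 256) {
    itil_error("itil_invalid_argument", "at most 256 classes fit in an 8-bit PNG")
  }
  png::writePNG((raster$grid - 1L) / 255, path)
  jsonlite::write_json(
    list(mpp = raster$mpp, origin_um = raster$origin_um,
         class_map = as.list(stats::setNames(seq_along(raster$classes) - 1L,
                                             raster$classes))),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_label_raster
#' @export
read_label_raster <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  grid <- matrix(as.integer(round(img * 255)) + 1L, nrow(img), ncol(img))
  classes <- names(sort(unlist(meta$class_map)))
  label_raster(grid, classes, meta$mpp, unlist(meta$origin_um))
}

#' Write / read point sets as CSV
#'
#' Columns `x_um, y_um, confidence, compartment`.
#'
#' @param points A [point_set()].
#' @param path CSV path.
#' @return `write_points_csv()` returns `path` invisibly;
#'   `read_points_csv()` returns a [point_set()].
#' @export
write_points_csv <- function(points, path) {
  utils::write.csv(as.data.frame(points), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_points_csv
#' @export
read_points_csv <- function(path) {
  as_point_set(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write / read point sets as GeoJSON
#'
#' QuPath-compatible Point features in micron coordinates, with
#' `confidence` and `classification` properties.
#'
#' @param points A [point_set()].
#' @param path GeoJSON path.
#' @return `write_points_geojson()` returns `path` invisibly;
#'   `read_points_geojson()` returns a [point_set()].
#' @export
write_points_geojson <- function(points, path) {
  features <- lapply(seq_len(nrow(points)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(points$x_um[i], points$y_um[i])),
         properties = list(
           confidence = points$confidence[i],
           classification = if (is.na(points$compartment[i])) NULL else
             list(name = points$compartment[i])))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_points_geojson
#' @export
read_points_geojson <- function(path) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (length(fc$features) == 0) return(point_set())
  xy <- t(vapply(fc$features, function(f) unlist(f$geometry$coordinates),
                 numeric(2)))
  conf <- vapply(fc$features, function(f) {
    c0 <- f$properties$confidence
    if (is.null(c0)) 1 else as.numeric(c0)
  }, numeric(1))
  comp <- vapply(fc$features, function(f) {
    cl <- f$properties$classification
    if (is.null(cl) || is.null(cl$name)) NA_character_ else as.character(cl$name)
  }, character(1))
  point_set(xy[, 1], xy[, 2], conf, comp)
}

#' Write / read a heatmap as 32-bit float TIFF
#'
#' @param heatmap Numeric matrix in [0, 1].
#' @param path TIFF path.
#' @return `write_heatmap_tiff()` returns `path` invisibly;
#'   `read_heatmap_tiff()` returns the matrix.
#' @export
write_heatmap_tiff <- function(heatmap, path) {
  tiff::writeTIFF(heatmap, path, bits.per.sample = 32)
  invisible(path)
}

#' @rdname write_heatmap_tiff
#' @export
read_heatmap_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' Read a pipeline configuration from YAML
#'
#' Recognised sections map onto the constructor arguments of
#' [detection_config()], [scoring_config()] and [flag_criteria()];
#' `tiling` holds `tile_size_px` and per-stage `overlap_px` values, and
#' `stain` holds the Macenko parameters. Absent entries keep their
#' defaults.
#'
#' @param path YAML file path.
#' @return List with `detection`, `scoring`, `criteria`, `tiling`, `stain`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(fn, args) do.call(fn, args[intersect(names(args), names(formals(fn)))])
  list(
    detection = build(detection_config, y$detection %||% list()),
    scoring = build(scoring_config, y$scoring %||% list()),
    criteria = build(flag_criteria, y$criteria %||% list()),
    tiling = utils::modifyList(list(tile_size_px = 512L,
                                    segmentation_overlap_px = 0L,
                                    detection_overlap_px = 64L),
                               y$tiling %||% list()),
    stain = utils::modifyList(list(beta_od_floor = 0.15, alpha = 1,
                                   io_percentile = 99),
                              y$stain %||% list())
  )
}
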