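#' Heatmap codec specification
#'
#' Parameters of the Gaussian point-to-heatmap encoding used to train and
#' decode the TIL detector: an isotropic Gaussian of standard deviation
#' `sigma_um` and peak `peak_value` is centred on each annotated point.
#'
#' @param sigma_um Gaussian standard deviation in microns (default 2, about
#'   a quarter of the ~8 um TIL nucleus diameter).
#' @param peak_value Peak value per point (default 1).
#' @param mpp Heatmap resolution in microns per pixel (default 0.25, i.e.
#'   40x magnification).
#' @return A `heatmap_spec` list.
#' @export
heatmap_spec <- function(sigma_um = 2.0, peak_value = 1.0, mpp = 0.25) {
  stopifnot_scalar_number(sigma_um, "sigma_um", positive = TRUE)
  stopifnot_scalar_number(mpp, "mpp", positive = TRUE)
  list(sigma_um = sigma_um, peak_value = peak_value, mpp = mpp)
}

#' Detection decoding configuration
#'
#' @param confidence_threshold Minimum peak value kept (default 0.35, the
#'   confidence gate selected by F1 sweep).
#' @param min_separation_um Minimum separation between decoded points
#'   (default 4, half the ~8 um TIL diameter).
#' @param nms_radius_um Radius of the cross-tile point NMS (default 4).
#' @return A `detection_config` list.
#' @export
detection_config <- function(confidence_threshold = 0.35,
                             min_separation_um = 4.0,
                             nms_radius_um = 4.0) {
  if (confidence_threshold < 0 || confidence_threshold > 1) {
    itil_error("itil_invalid_argument", "confidence_threshold must lie in [0, 1]")
  }
  stopifnot_scalar_number(min_separation_um, "min_separation_um", positive = TRUE)
  stopifnot_scalar_number(nms_radius_um, "nms_radius_um", positive = TRUE)
  list(confidence_threshold = confidence_threshold,
       min_separation_um = min_separation_um,
       nms_radius_um = nms_radius_um)
}

# add an isotropic Gaussian of amplitude `amp` centred at 0-based pixel
# (px, py) to `heat`, combining by pixel-wise maximum; window cut at 4 sigma
gauss_paint <- function(heat, px, py, sigma_px, amp = 1) {
  r <- ceiling(4 * sigma_px)
  h <- nrow(heat); w <- ncol(heat)
  cx <- max(0, px - r):min(w - 1, px + r)
  cy <- max(0, py - r):min(h - 1, py + r)
  if (length(cx) == 0 || length(cy) == 0) return(heat)
  g <- amp * exp(-(outer((cy - py)^2, (cx - px)^2, "+")) / (2 * sigma_px^2))
  heat[cy + 1, cx + 1] <- pmax(heat[cy + 1, cx + 1], g)
  heat
}

#' Encode points as a Gaussian heatmap
#'
#' Renders a training-target heatmap: each point contributes an isotropic
#' 2D Gaussian of peak `spec$peak_value` at its containing pixel;
#' overlapping contributions combine by pixel-wise maximum (so the peak
#' value, which doubles as detection confidence, stays in [0, 1]).
#'
#' @param points A [point_set()] in microns.
#' @param extent_px `(width, height)` of the heatmap in pixels.
#' @param spec A [heatmap_spec()].
#' @param origin_um Micron offset of heatmap pixel (0, 0).
#' @return Numeric matrix `height x width` with values in [0, 1].
#' @export
encode_points <- function(points, extent_px, spec = heatmap_spec(),
                          origin_um = c(0, 0)) {
  heat <- matrix(0, extent_px[2], extent_px[1])
  if (nrow(points) == 0) return(heat)
  sigma_px <- spec$sigma_um / spec$mpp
  px <- floor((points$x_um - origin_um[1]) / spec$mpp)
  py <- floor((points$y_um - origin_um[2]) / spec$mpp)
  for (i in seq_len(nrow(points))) {
    heat <- gauss_paint(heat, px[i], py[i], sigma_px, spec$peak_value)
  }
  pmin(pmax(heat, 0), 1)
}

# sliding maximum over a (2r+1)^2 square window (grey-scale dilation);
# EBImage's C implementation for nontrivial windows, shifted pmax otherwise
sliding_max <- function(m, r) {
  if (r < 1) return(m)
  h <- nrow(m); w <- ncol(m)
  if (2L * r + 1L <= min(h, w)) {
    return(EBImage::dilate(m, EBImage::makeBrush(2L * r + 1L, shape = "box")))
  }
  res <- m
  for (k in seq_len(min(r, w - 1L))) {    # horizontal pass
    res <- pmax(res,
                cbind(m[, (k + 1):w, drop = FALSE], matrix(-Inf, h, k)),
                cbind(matrix(-Inf, h, k), m[, 1:(w - k), drop = FALSE]))
  }
  m2 <- res
  for (k in seq_len(min(r, h - 1L))) {    # vertical pass
    res <- pmax(res,
                rbind(m2[(k + 1):h, , drop = FALSE], matrix(-Inf, k, w)),
                rbind(matrix(-Inf, k, w), m2[1:(h - k), , drop = FALSE]))
  }
  res
}

#' Decode a heatmap into confidence-scored points
#'
#' Blob decoding by local-maximum extraction: pixels that attain the sliding
#' maximum of their neighbourhood (radius `min_separation_um`), exceed the
#' confidence gate, and survive point NMS at `min_separation_um` become
#' detections. Each point's confidence is its peak heatmap value; its
#' coordinate is the peak pixel centre (sub-pixel refinement is unnecessary
#' at 0.25 um quantisation against a 4 um match radius).
#'
#' @param heatmap Numeric matrix with values in [0, 1].
#' @param config A [detection_config()].
#' @param mpp Heatmap resolution (microns per pixel).
#' @param origin_um Micron offset of heatmap pixel (0, 0).
#' @return A [point_set()] sorted by confidence descending.
#' @export
decode_heatmap <- function(heatmap, config = detection_config(), mpp = 0.25,
                           origin_um = c(0, 0)) {
  if (max(heatmap) < config$confidence_threshold || max(heatmap) <= 0) {
    return(point_set())
  }
  r <- max(1L, as.integer(round(config$min_separation_um / mpp)))
  mx <- sliding_max(heatmap, r)
  cand <- which(heatmap >= config$confidence_threshold & heatmap >= mx &
                  heatmap > 0, arr.ind = TRUE)
  if (nrow(cand) == 0) return(point_set())
  pts <- point_set(
    x_um = origin_um[1] + (cand[, 2] - 0.5) * mpp,
    y_um = origin_um[2] + (cand[, 1] - 0.5) * mpp,
    confidence = heatmap[cand]
  )
  point_nms(pts, config$min_separation_um)
}

#' Point-based non-maximum suppression
#'
#' Greedy confidence-descending selection: points are visited from highest
#' to lowest confidence (ties broken by (y, x) lexicographic order for
#' reproducibility); a point is suppressed if it lies within `radius_um` of
#' an already-selected point. Idempotent; output pairwise distances all
#' exceed the radius.
#'
#' @param points A [point_set()].
#' @param radius_um Suppression radius in microns.
#' @return The surviving [point_set()], sorted by confidence descending.
#' @export
point_nms <- function(points, radius_um) {
  stopifnot_scalar_number(radius_um, "radius_um", positive = TRUE)
  n <- nrow(points)
  if (n <= 1) return(points)
  ord <- order(-points$confidence, points$y_um, points$x_um)
  x <- points$x_um[ord]; y <- points$y_um[ord]
  keep <- logical(n)
  kx <- numeric(0); ky <- numeric(0)
  r2 <- radius_um^2
  for (i in seq_len(n)) {
    if (length(kx) == 0 || all((kx - x[i])^2 + (ky - y[i])^2 > r2)) {
      keep[i] <- TRUE
      kx <- c(kx, x[i]); ky <- c(ky, y[i])
    }
  }
  out <- points[ord, , drop = FALSE][keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("point_set", "data.frame")
  out
}

#' Merge per-tile detections into a slide-level point set
#'
#' Maps tile-local pixel detections into the shared micron frame and runs
#' point NMS so a TIL visible in two overlapping tiles is counted once.
#'
#' @param per_tile List (one entry per tile in plan order) of data frames
#'   with tile-local 0-based pixel columns `x_px`, `y_px` and `confidence`;
#'   `NULL` entries mean no detections in that tile.
#' @param plan The [plan_tiles()] plan the tiles came from.
#' @param config A [detection_config()]; its `nms_radius_um` is used.
#' @return A [point_set()] in global micron coordinates.
#' @export
merge_tile_detections <- function(per_tile, plan, config = detection_config()) {
  if (length(per_tile) != nrow(plan$tiles)) {
    itil_error("itil_invalid_argument",
               "one detection set per planned tile is required (use NULL for empty tiles)")
  }
  parts <- lapply(seq_along(per_tile), function(i) {
    d <- per_tile[[i]]
    if (is.null(d) || nrow(d) == 0) return(NULL)
    t <- plan$tiles[i, ]
    if (any(d$x_px < 0) || any(d$y_px < 0) ||
        any(d$x_px >= t$px1 - t$px0) || any(d$y_px >= t$py1 - t$py0)) {
      itil_error("itil_invalid_argument",
                 sprintf("tile %d has detections outside its bounds", i))
    }
    data.frame(x_um = t$ux0 + (d$x_px + 0.5) * plan$mpp,
               y_um = t$uy0 + (d$y_px + 0.5) * plan$mpp,
               confidence = d$confidence)
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (length(parts) == 0) return(point_set())
  pooled <- do.call(rbind, parts)
  point_nms(point_set(pooled$x_um, pooled$y_um, pooled$confidence),
            config$nms_radius_um)
}
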