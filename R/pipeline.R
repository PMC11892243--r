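# Stage runners: tile planning -> per-tile backend inference ->
# reconstruction, at each stage's working resolution, plus the end-to-end
# slide and patient scoring entry points.

slide_extent_um <- function(slide) {
  if (inherits(slide, "slide_source")) return(slide$extent_um)
  if (inherits(slide, "rgb_raster")) {
    return(c(dim(slide$rgb)[2], dim(slide$rgb)[1]) * slide$mpp)
  }
  itil_error("itil_invalid_argument", "slide must be a slide_source or rgb_raster")
}

# fetch one RGB tile at the requested resolution
get_tile <- function(slide, px0, py0, w_px, h_px, mpp) {
  if (inherits(slide, "slide_source")) {
    return(slide$render(px0, py0, w_px, h_px, mpp))
  }
  if (mpp == slide$mpp) {
    return(slide$rgb[(py0 + 1):(py0 + h_px), (px0 + 1):(px0 + w_px), , drop = FALSE])
  }
  f <- mpp / slide$mpp
  if (abs(f - round(f)) > 1e-9 || f < 1) {
    itil_error("itil_invalid_argument",
               "in-memory slides support only integer downsampling factors")
  }
  f <- as.integer(round(f))
  sub <- slide$rgb[(py0 * f + 1):((py0 + h_px) * f),
                   (px0 * f + 1):((px0 + w_px) * f), , drop = FALSE]
  downsample_rgb(sub, f)
}

run_stage_segmentation <- function(slide, backend, tile_size_px, overlap_px,
                                   normalise_stains, stain_reference) {
  mpp <- backend$input_mpp
  ext_um <- slide_extent_um(slide)
  extent_px <- pmax(1L, as.integer(round(ext_um / mpp)))
  plan <- plan_tiles(extent_px, tile_size_px, overlap_px, mpp)
  stain_failures <- 0L
  preds <- vector("list", nrow(plan$tiles))
  for (i in seq_len(nrow(plan$tiles))) {
    t <- plan$tiles[i, ]
    rgb <- get_tile(slide, t$px0, t$py0, t$px1 - t$px0, t$py1 - t$py0, mpp)
    if (normalise_stains) {
      rgb <- tryCatch(macenko_normalize(rgb, stain_reference),
                      itil_stain_failure = function(e) {
                        stain_failures <<- stain_failures + 1L
                        rgb
                      })
    }
    prob <- tryCatch(backend$predict(rgb, mpp), error = function(e) {
      itil_error("itil_backend_failure",
                 sprintf("backend '%s' failed on tile %d: %s",
                         backend$name, i, conditionMessage(e)))
    })
    k <- dim(prob)[3]
    pm <- matrix(prob, ncol = k)
    preds[[i]] <- matrix(max.col(pm, ties.method = "first"),
                         nrow(prob), ncol(prob))
  }
  out <- reconstruct_raster(preds, plan, backend$classes)
  attr(out, "stain_failures") <- stain_failures
  out
}

#' Run broad cancer segmentation over a slide
#'
#' Stage 1 of the pipeline: plans 512 px tiles at 4 MPP (2.5x), runs the
#' broad backend on each tile, takes the per-pixel argmax and reconstructs
#' a slide-level cancer/other mask.
#'
#' @param slide A [slide_source()] or [rgb_raster()].
#' @param backend A `"broad"` stage backend (default: the registered toy
#'   backend).
#' @param tile_size_px,overlap_px Tiling parameters (defaults 512 / 0).
#' @param normalise_stains Apply [macenko_normalize()] per tile before
#'   inference; failed tiles are counted (attribute `stain_failures`) and
#'   passed through unnormalised.
#' @param stain_reference Reference stains for normalisation.
#' @return A [label_raster()] with classes `other`/`cancer` at 4 MPP and a
#'   `stain_failures` attribute.
#' @export
run_broad_segmentation <- function(slide, backend = get_backend("broad", "toy"),
                                   tile_size_px = 512L, overlap_px = 0L,
                                   normalise_stains = FALSE,
                                   stain_reference = stain_reference_he()) {
  run_stage_segmentation(slide, backend, tile_size_px, overlap_px,
                         normalise_stains, stain_reference)
}

# nearest-neighbour class lookup of `raster` on the pixel grid of a target
# resolution/extent (shared micron frame)
lookup_grid <- function(raster, out_w, out_h, mpp) {
  sx <- pmin(ncol(raster$grid) - 1L,
             pmax(0L, floor(((seq_len(out_w) - 0.5) * mpp - raster$origin_um[1]) / raster$mpp)))
  sy <- pmin(nrow(raster$grid) - 1L,
             pmax(0L, floor(((seq_len(out_h) - 0.5) * mpp - raster$origin_um[2]) / raster$mpp)))
  raster$grid[sy + 1L, sx + 1L, drop = FALSE]
}

#' Run tumour/stroma/necrosis segmentation within cancerous tissue
#'
#' Stage 2: tiles the slide at 0.5 MPP (20x), runs the TSN backend and
#' reconstructs, then restricts the result to broadly cancerous tissue —
#' pixels outside the broad cancer mask (nearest-neighbour lookup in the
#' shared micron frame) are set to `"other"` and never count as tumour,
#' stroma or necrosis.
#'
#' @param slide A [slide_source()] or [rgb_raster()].
#' @param broad_mask The 4 MPP [run_broad_segmentation()] output, in the
#'   same micron frame.
#' @param backend A `"tsn"` stage backend.
#' @inheritParams run_broad_segmentation
#' @return A [label_raster()] with classes
#'   `other`/`tumour`/`stroma`/`necrosis` at 0.5 MPP.
#' @export
run_tsn_segmentation <- function(slide, broad_mask,
                                 backend = get_backend("tsn", "toy"),
                                 tile_size_px = 512L, overlap_px = 0L,
                                 normalise_stains = FALSE,
                                 stain_reference = stain_reference_he()) {
  if (!isTRUE(all(abs(broad_mask$origin_um) < 1e-9))) {
    itil_error("itil_invalid_argument",
               "broad mask and slide must share the micron frame (origin 0)")
  }
  tsn <- run_stage_segmentation(slide, backend, tile_size_px, overlap_px,
                                normalise_stains, stain_reference)
  cancer <- lookup_grid(broad_mask, ncol(tsn$grid), nrow(tsn$grid), tsn$mpp) ==
    raster_class_id(broad_mask, "cancer")
  other <- raster_class_id(tsn, "other")
  tsn$grid[!cancer] <- other
  tsn
}

#' Run TIL point detection within cancerous tissue
#'
#' Stage 3: tiles the slide at 0.25 MPP (40x) with a 64 px overlap so TILs
#' straddling tile seams are fully visible in at least one tile, decodes
#' each tile's heatmap ([decode_heatmap()]), merges detections across tiles
#' with point NMS ([merge_tile_detections()]), and finally discards points
#' outside the broad cancer mask. Tiles with no cancerous tissue are
#' skipped.
#'
#' @param slide A [slide_source()] or [rgb_raster()].
#' @param broad_mask The 4 MPP broad cancer mask.
#' @param backend A `"til"` stage backend.
#' @param config A [detection_config()].
#' @param tile_size_px,overlap_px Tiling parameters (defaults 512 / 64).
#' @return A [point_set()] of TIL detections in global micron coordinates.
#' @export
run_til_detection <- function(slide, broad_mask,
                              backend = get_backend("til", "toy"),
                              config = detection_config(),
                              tile_size_px = 512L, overlap_px = 64L) {
  mpp <- backend$input_mpp
  ext_um <- slide_extent_um(slide)
  extent_px <- pmax(1L, as.integer(round(ext_um / mpp)))
  plan <- plan_tiles(extent_px, tile_size_px, overlap_px, mpp)
  cancer_id <- raster_class_id(broad_mask, "cancer")
  per_tile <- vector("list", nrow(plan$tiles))
  for (i in seq_len(nrow(plan$tiles))) {
    t <- plan$tiles[i, ]
    # broad-mask window covering the tile (coarse check to skip empty tiles)
    bx <- floor(c(t$ux0, t$ux1 - 1e-9) / broad_mask$mpp)
    by <- floor(c(t$uy0, t$uy1 - 1e-9) / broad_mask$mpp)
    bx <- pmin(pmax(bx, 0), ncol(broad_mask$grid) - 1L)
    by <- pmin(pmax(by, 0), nrow(broad_mask$grid) - 1L)
    if (!any(broad_mask$grid[(by[1] + 1):(by[2] + 1),
                             (bx[1] + 1):(bx[2] + 1)] == cancer_id)) next
    rgb <- get_tile(slide, t$px0, t$py0, t$px1 - t$px0, t$py1 - t$py0, mpp)
    heat <- tryCatch(backend$predict(rgb, mpp), error = function(e) {
      itil_error("itil_backend_failure",
                 sprintf("backend '%s' failed on tile %d: %s",
                         backend$name, i, conditionMessage(e)))
    })
    local <- decode_heatmap(heat, config, mpp, origin_um = c(0, 0))
    if (nrow(local) > 0) {
      per_tile[[i]] <- data.frame(x_px = local$x_um / mpp - 0.5,
                                  y_px = local$y_um / mpp - 0.5,
                                  confidence = local$confidence)
    }
  }
  merged <- merge_tile_detections(per_tile, plan, config)
  if (nrow(merged) == 0) return(merged)
  keep <- raster_class_at(broad_mask, merged$x_um, merged$y_um) == "cancer"
  out <- merged[keep & !is.na(keep), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("point_set", "data.frame")
  out
}

# fraction of detected tissue (non-white pixels at 4 MPP) that is cancerous
cancer_fraction_of_tissue <- function(slide, broad_mask, white_level = 235) {
  ext <- raster_extent_px(broad_mask)
  rgb <- get_tile(slide, 0L, 0L, ext[1], ext[2], broad_mask$mpp)
  lum <- (rgb[, , 1] + rgb[, , 2] + rgb[, , 3]) / 3
  tissue <- lum < white_level
  if (!any(tissue)) return(0)
  cancer <- broad_mask$grid == raster_class_id(broad_mask, "cancer")
  sum(cancer & tissue) / sum(tissue)
}

#' Score one slide end to end
#'
#' Runs the full pipeline on a slide: broad cancer segmentation (4 MPP),
#' TSN segmentation within cancer (0.5 MPP), TIL detection within cancer
#' (0.25 MPP), compartment assignment, HPF-equivalent field scoring over
#' the tumour mask, and reliability flagging.
#'
#' @param slide A [slide_source()] or [rgb_raster()].
#' @param slide_id Identifier carried into outputs.
#' @param backends Named list with `broad`, `tsn`, `til` backends
#'   (defaults: registered toy backends).
#' @param det_config A [detection_config()].
#' @param config A [scoring_config()].
#' @param criteria [flag_criteria()] for reliability flagging.
#' @param normalise_stains Apply per-tile Macenko normalisation in the
#'   segmentation stages.
#' @param keep_rasters Keep the (large) predicted masks on the result.
#' @return A `slide_score`: list with `fields` (per-field table),
#'   `eligible_count`, `points` (compartment-labelled detections),
#'   `metrics`, `flags` (a [flag_slide()] report) and optionally the masks.
#' @export
score_slide <- function(slide, slide_id = "slide",
                        backends = list(broad = get_backend("broad", "toy"),
                                        tsn = get_backend("tsn", "toy"),
                                        til = get_backend("til", "toy")),
                        det_config = detection_config(),
                        config = scoring_config(),
                        criteria = flag_criteria(),
                        normalise_stains = FALSE,
                        keep_rasters = FALSE) {
  broad <- run_broad_segmentation(slide, backends$broad,
                                  normalise_stains = normalise_stains)
  tsn <- run_tsn_segmentation(slide, broad, backends$tsn,
                              normalise_stains = normalise_stains)
  pts <- run_til_detection(slide, broad, backends$til, det_config)
  pts <- assign_compartment(pts, tsn)
  grid_fields <- build_field_grid(tsn, config)
  fields <- score_fields(grid_fields, tsn, pts, config)
  metrics <- list(
    tumour_area_mm2 = class_area_mm2(tsn, "tumour"),
    eligible_field_count = sum(fields$eligible),
    cancer_fraction_of_tissue = cancer_fraction_of_tissue(slide, broad),
    stain_failures = attr(broad, "stain_failures") %||% 0L
  )
  out <- list(slide_id = slide_id, fields = fields,
              eligible_count = metrics$eligible_field_count,
              points = pts, metrics = metrics,
              flags = flag_slide(metrics, criteria))
  if (keep_rasters) {
    out$broad <- broad
    out$tsn <- tsn
  }
  structure(out, class = "slide_score")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.slide_score <- function(x, ...) {
  cat(sprintf("<slide_score> '%s': %d fields (%d eligible), %d detections, tumour %.2f mm^2%s\n",
              x$slide_id, nrow(x$fields), x$eligible_count, nrow(x$points),
              x$metrics$tumour_area_mm2,
              if (x$flags$flagged) " [FLAGGED]" else ""))
  invisible(x)
}

#' Score a patient from one or more slides
#'
#' Pools eligible fields across the patient's slides into the AI iTIL
#' score ([ai_itil_score()]) and merges slide flags; a patient with no
#' eligible field is flagged with an undefined score.
#'
#' @param slide_scores List of [score_slide()] results.
#' @param patient_id Identifier.
#' @param config A [scoring_config()].
#' @return A `patient_score` with added `patient_id`, `n_slides` and
#'   `flagged`.
#' @export
score_patient <- function(slide_scores, patient_id = "patient",
                          config = scoring_config()) {
  ps <- ai_itil_score(slide_scores, config)
  ps$patient_id <- patient_id
  ps$n_slides <- length(slide_scores)
  ps$flagged <- ps$undefined ||
    any(vapply(slide_scores, function(s) s$flags$flagged, logical(1)))
  ps
}
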