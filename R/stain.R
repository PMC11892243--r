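#' Reference H&E stain basis
#'
#' A widely used literature reference for haematoxylin and eosin optical
#' density vectors, together with reference maximum concentrations used for
#' rescaling. Columns are unit-norm OD vectors (H first, then E).
#'
#' @return A `stain_reference`: list with `stain_matrix` (3 x 2) and
#'   `max_concentrations` (length 2).
#' @export
stain_reference_he <- function() {
  m <- matrix(c(0.5626, 0.7201, 0.4062,
                0.2159, 0.8012, 0.5581), nrow = 3)
  structure(list(stain_matrix = m, max_concentrations = c(1.9705, 1.0308)),
            class = "stain_reference")
}

# RGB (0-255) -> optical density, guarding log(0)
rgb_to_od <- function(v, io = 255) -log(pmax(v, 1) / io)

#' Estimate H&E stain vectors from a tile (Macenko)
#'
#' Estimates the two-stain optical-density basis from the singular plane of
#' the tile's OD pixels: background-like pixels (any OD channel below
#' `beta_od_floor`) are discarded, the remaining OD cloud is projected onto
#' its top two principal directions, and the stain vectors are read off at
#' the `alpha` / `100 - alpha` percentiles of the projection angle. Vectors
#' are ordered so the haematoxylin-like vector comes first.
#'
#' @param rgb Numeric `h x w x 3` array, 8-bit scale (0-255).
#' @param beta_od_floor OD transparency floor below which pixels count as
#'   background (default 0.15).
#' @param alpha Angular percentile for the extreme stains (default 1).
#' @param io_percentile Percentile used for the maximum-concentration scale
#'   (default 99).
#' @param min_tissue_px Minimum number of tissue pixels required.
#' @return A `stain_reference` estimated from the tile, with attribute
#'   `concentrations` (2 x n matrix for the whole tile).
#' @export
macenko_fit <- function(rgb, beta_od_floor = 0.15, alpha = 1,
                        io_percentile = 99, min_tissue_px = 50) {
  od <- cbind(as.vector(rgb_to_od(rgb[, , 1])),
              as.vector(rgb_to_od(rgb[, , 2])),
              as.vector(rgb_to_od(rgb[, , 3])))
  tissue <- od[od[, 1] > beta_od_floor & od[, 2] > beta_od_floor &
                 od[, 3] > beta_od_floor, , drop = FALSE]
  if (nrow(tissue) < min_tissue_px) {
    itil_error("itil_stain_failure",
               "stain estimation failed: tile is background/white (no tissue OD)")
  }
  eg <- eigen(stats::cov(tissue), symmetric = TRUE)
  if (eg$values[2] <= 1e-12) {
    itil_error("itil_stain_failure",
               "stain estimation failed: degenerate OD covariance (single stain?)")
  }
  v <- eg$vectors[, 1:2]
  # orient the plane basis so tissue projections are predominantly positive
  for (j in 1:2) if (sum(tissue %*% v[, j]) < 0) v[, j] <- -v[, j]
  proj <- tissue %*% v
  phi <- atan2(proj[, 2], proj[, 1])
  ang <- stats::quantile(phi, c(alpha, 100 - alpha) / 100, names = FALSE)
  v1 <- v %*% c(cos(ang[1]), sin(ang[1]))
  v2 <- v %*% c(cos(ang[2]), sin(ang[2]))
  he <- if (v1[1] > v2[1]) cbind(v1, v2) else cbind(v2, v1)
  dimnames(he) <- NULL

  conc <- solve(crossprod(he), crossprod(he, t(od)))   # least-squares unmixing
  maxc <- apply(conc, 1, stats::quantile, probs = io_percentile / 100, names = FALSE)
  ref <- structure(list(stain_matrix = he, max_concentrations = maxc),
                   class = "stain_reference")
  attr(ref, "concentrations") <- conc
  ref
}

#' Macenko stain normalisation
#'
#' Re-expresses a tile in a reference H&E stain basis to lessen
#' inter-scanner colour variability: stain vectors are estimated from the
#' tile ([macenko_fit()]), per-pixel concentrations are rescaled so their
#' upper percentile matches the reference maxima, and the image is
#' re-composited with the reference stain matrix.
#'
#' @param rgb Numeric `h x w x 3` array on the 0-255 scale.
#' @param reference Target [stain_reference_he()] (or any `stain_reference`).
#' @param io_percentile Concentration-scaling percentile (default 99).
#' @param beta_od_floor Background OD floor (default 0.15).
#' @param alpha Angular percentile (default 1).
#' @return Normalised `h x w x 3` array, same shape, 0-255.
#' @seealso [macenko_fit()] for the estimation step and failure conditions.
#' @export
macenko_normalize <- function(rgb, reference = stain_reference_he(),
                              io_percentile = 99, beta_od_floor = 0.15,
                              alpha = 1) {
  fit <- macenko_fit(rgb, beta_od_floor = beta_od_floor, alpha = alpha,
                     io_percentile = io_percentile)
  conc <- attr(fit, "concentrations")
  scale <- reference$max_concentrations / fit$max_concentrations
  conc <- conc * scale
  od_new <- reference$stain_matrix %*% conc
  out <- 255 * exp(-od_new)
  out <- pmin(pmax(out, 0), 255)
  d <- dim(rgb)
  array(c(matrix(out[1, ], d[1], d[2]),
          matrix(out[2, ], d[1], d[2]),
          matrix(out[3, ], d[1], d[2])), dim = d)
}
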