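# Shared fixture builders (all programmatic; no stored data).

# uniform random points with a guaranteed minimum pairwise separation
random_separated_points <- function(n, extent_um, min_sep_um, confidence = 1) {
  xs <- numeric(0); ys <- numeric(0)
  guard <- 0
  while (length(xs) < n && guard < 200 * n) {
    guard <- guard + 1
    x <- stats::runif(1, 2, extent_um[1] - 2)
    y <- stats::runif(1, 2, extent_um[2] - 2)
    if (length(xs) == 0 || all((xs - x)^2 + (ys - y)^2 > min_sep_um^2)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  point_set(xs, ys, confidence = rep_len(confidence, length(xs)))
}

# independent quadratic greedy-NMS oracle (explicit loops, same tie rule)
nms_oracle <- function(points, radius_um) {
  n <- nrow(points)
  if (n <= 1) return(points)
  ord <- order(-points$confidence, points$y_um, points$x_um)
  sel <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in sel) {
      d2 <- (points$x_um[i] - points$x_um[j])^2 +
        (points$y_um[i] - points$y_um[j])^2
      if (d2 <= radius_um^2) { ok <- FALSE; break }
    }
    if (ok) sel <- c(sel, i)
  }
  out <- points[sel, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("point_set", "data.frame")
  out
}

# small label raster of one class with optional rectangle of another
rect_raster <- function(w, h, mpp, classes = c("other", "tumour"),
                        fill = 1L, rect = NULL, rect_class = 2L) {
  g <- matrix(fill, h, w)
  if (!is.null(rect)) {
    g[(rect[2] + 1):rect[4], (rect[1] + 1):rect[3]] <- rect_class
  }
  label_raster(g, classes, mpp)
}

# render a toy-palette RGB raster from a label raster (no jitter)
palette_rgb_raster <- function(raster, class_to_palette) {
  pal <- toy_palette()
  d <- dim(raster$grid)
  rgb <- array(0, c(d[1], d[2], 3))
  for (ch in 1:3) {
    rgb[, , ch] <- matrix(pal[class_to_palette[raster$grid], ch], d[1], d[2])
  }
  rgb_raster(rgb, raster$mpp, raster$origin_um)
}

# compose an RGB image from known stain concentrations
compose_stain_image <- function(stain_matrix, c1, c2, w, h) {
  od <- stain_matrix %*% rbind(c1, c2)
  rgb <- array(0, c(h, w, 3))
  for (ch in 1:3) rgb[, , ch] <- matrix(255 * exp(-od[ch, ]), h, w)
  rgb
}

# small synthetic slide shared by the slower pipeline tests
small_scene <- local({
  cache <- NULL
  function(lambda_tumour = 60, seed = 3) {
    key <- paste(lambda_tumour, seed)
    if (!is.null(cache) && cache$key == key) return(cache$value)
    lay <- generate_layout(layout_spec(extent_um = c(1200, 1200), seed = seed))
    tils <- plant_tils(lay$tsn, plant_spec(lambda_tumour = lambda_tumour,
                                           seed = seed + 1))
    value <- list(layout = lay, tils = tils, source = slide_source(lay, tils))
    cache <<- list(key = key, value = value)
    value
  }
})
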