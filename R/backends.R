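#' Toy rendering palette
#'
#' Fixed colours used by the synthetic slide renderer and, symmetrically, by
#' the deterministic reference backends that classify pixels by
#' nearest-palette colour. The renderer adds a small seeded jitter so the
#' toy backends are near-perfect but exercise real error paths.
#'
#' @return Named 3-column matrix of RGB colours (0-255).
#' @export
toy_palette <- function() {
  rbind(
    background = c(242, 242, 242),
    normal     = c(205, 170, 205),
    tumour     = c(150,  60, 130),
    stroma     = c(235, 150, 170),
    necrosis   = c(160, 150,  90),
    til        = c( 45,  45, 140)
  )
}

# nearest-palette class index for every pixel of an rgb array
nearest_palette_class <- function(rgb, palette = toy_palette()) {
  d <- dim(rgb)
  n <- d[1] * d[2]
  r <- as.vector(rgb[, , 1]); g <- as.vector(rgb[, , 2]); b <- as.vector(rgb[, , 3])
  best <- rep.int(1L, n)
  bestd <- (r - palette[1, 1])^2 + (g - palette[1, 2])^2 + (b - palette[1, 3])^2
  for (k in 2:nrow(palette)) {
    dk <- (r - palette[k, 1])^2 + (g - palette[k, 2])^2 + (b - palette[k, 3])^2
    upd <- dk < bestd
    best[upd] <- k
    bestd[upd] <- dk[upd]
  }
  matrix(best, d[1], d[2])
}

#' Backend contracts for the three model stages
#'
#' A backend is a list with fields `stage` (`"broad"`, `"tsn"` or `"til"`),
#' `name`, `input_mpp` (4, 0.5 and 0.25 respectively), `classes` (for the
#' segmentation stages) and `predict(rgb, mpp)` returning per-pixel class
#' probabilities (`h x w x K`) for segmentation stages or a heatmap
#' (`h x w` in [0, 1]) for the TIL stage. Trained-network adapters plug in
#' behind the same contract; the toy backends below make the pipeline
#' executable and testable without trained weights.
#'
#' @param stage One of `"broad"`, `"tsn"`, `"til"`.
#' @param name Registry name.
#' @param predict Prediction function `(rgb, mpp) -> array`.
#' @param classes Class names for segmentation stages.
#' @param input_mpp Working resolution of the stage.
#' @return A `til_backend` object.
#' @export
backend_spec <- function(stage, name, predict, classes = NULL,
                         input_mpp = c(broad = 4, tsn = 0.5, til = 0.25)[[stage]]) {
  stage <- match.arg(stage, c("broad", "tsn", "til"))
  structure(list(stage = stage, name = name, input_mpp = input_mpp,
                 tile_size_px = 512L, classes = classes, predict = predict),
            class = "til_backend")
}

.backend_registry <- new.env(parent = emptyenv())

#' Register / fetch backends by name
#'
#' A small plug-in registry so pipelines and the command line can address
#' backends by `"<stage>/<name>"`.
#'
#' @param backend A [backend_spec()] object.
#' @return `register_backend()` returns the backend invisibly;
#'   `get_backend()` returns the registered backend.
#' @export
register_backend <- function(backend) {
  assign(paste(backend$stage, backend$name, sep = "/"), backend,
         envir = .backend_registry)
  invisible(backend)
}

#' @rdname register_backend
#' @param stage,name Stage and registry name of the backend to fetch.
#' @export
get_backend <- function(stage, name) {
  key <- paste(stage, name, sep = "/")
  if (!exists(key, envir = .backend_registry)) {
    itil_error("itil_invalid_argument", sprintf("no backend registered as '%s'", key))
  }
  get(key, envir = .backend_registry)
}

#' Deterministic reference backends
#'
#' `toy_broad_backend()` and `toy_tsn_backend()` classify each pixel by its
#' nearest [toy_palette()] colour: tumour/stroma/necrosis/TIL colours count
#' as broadly cancerous tissue; background and normal tissue do not.
#' `toy_til_backend()` emits a pseudo-heatmap by matched filtering: pixels
#' close to the TIL palette colour form a mask which is correlated with a
#' disk template of the TIL radius, giving values near 1 at TIL centres.
#' All three are pure functions of their inputs.
#'
#' @param palette Rendering palette (default [toy_palette()]).
#' @param til_radius_um TIL disk radius for the matched filter (default 3).
#' @param colour_tol Maximum Euclidean RGB distance to the TIL colour
#'   (default 60).
#' @return A [backend_spec()] backend.
#' @export
toy_broad_backend <- function(palette = toy_palette()) {
  cancerous <- c("tumour", "stroma", "necrosis", "til")
  predict <- function(rgb, mpp) {
    cls <- nearest_palette_class(rgb, palette)
    cancer <- matrix(as.numeric(rownames(palette)[cls] %in% cancerous),
                     nrow(cls), ncol(cls))
    array(c(1 - cancer, cancer), c(nrow(cls), ncol(cls), 2))
  }
  backend_spec("broad", "toy", predict, classes = c("other", "cancer"))
}

#' @rdname toy_broad_backend
#' @export
toy_tsn_backend <- function(palette = toy_palette()) {
  # TIL-coloured pixels are lymphocytes sitting in whatever compartment
  # surrounds them; the toy renderer only paints them at the detection
  # resolution, so at 0.5 MPP every pixel maps cleanly to a tissue colour.
  map <- c(background = "other", normal = "other", tumour = "tumour",
           stroma = "stroma", necrosis = "necrosis", til = "tumour")
  classes <- c("other", "tumour", "stroma", "necrosis")
  predict <- function(rgb, mpp) {
    cls <- nearest_palette_class(rgb, palette)
    id <- match(map[rownames(palette)[cls]], classes)
    out <- array(0, c(nrow(cls), ncol(cls), length(classes)))
    for (k in seq_along(classes)) out[, , k] <- as.numeric(matrix(id, nrow(cls)) == k)
    out
  }
  backend_spec("tsn", "toy", predict, classes = classes)
}

#' @rdname toy_broad_backend
#' @export
toy_til_backend <- function(palette = toy_palette(), til_radius_um = 3,
                            colour_tol = 60) {
  til_col <- palette["til", ]
  predict <- function(rgb, mpp) {
    d2 <- (rgb[, , 1] - til_col[1])^2 + (rgb[, , 2] - til_col[2])^2 +
      (rgb[, , 3] - til_col[3])^2
    hit <- d2 <= colour_tol^2
    if (!any(hit)) return(matrix(0, nrow(d2), ncol(d2)))
    mask <- matrix(as.numeric(hit), nrow(d2), ncol(d2))
    r_px <- max(1L, as.integer(round(til_radius_um / mpp)))
    brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
    heat <- EBImage::filter2(mask, brush / sum(brush), boundary = 0)
    pmin(pmax(as.matrix(heat), 0), 1)
  }
  backend_spec("til", "toy", predict)
}

register_default_backends <- function() {
  register_backend(toy_broad_backend())
  register_backend(toy_tsn_backend())
  register_backend(toy_til_backend())
}

.onLoad <- function(libname, pkgname) {
  register_default_backends()
}
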