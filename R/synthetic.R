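#' Synthetic slide layout specification
#'
#' Describes a synthetic H&E slide: a union of smooth random blobs of
#' broadly cancerous tissue surrounded by a rim of normal tissue on a white
#' background, with the cancerous region partitioned into tumour, stroma
#' and necrosis at requested area fractions. Everything is a pure function
#' of the seed.
#'
#' @param extent_um Slide extent `(width, height)` in microns.
#' @param n_blobs Number of cancer blobs.
#' @param tsn_fractions Named or positional fractions of tumour, stroma and
#'   necrosis within cancer; must sum to 1.
#' @param seed Integer seed.
#' @return A `layout_spec` list.
#' @export
layout_spec <- function(extent_um = c(2000, 2000), n_blobs = 5,
                        tsn_fractions = c(tumour = 0.6, stroma = 0.35, necrosis = 0.05),
                        seed = 1) {
  if (abs(sum(tsn_fractions) - 1) > 1e-9) {
    itil_error("itil_invalid_argument", "tsn_fractions must sum to 1")
  }
  list(extent_um = as.numeric(extent_um), n_blobs = as.integer(n_blobs),
       tsn_fractions = as.numeric(tsn_fractions), seed = as.integer(seed))
}

# internal geometry resolution: smooth mm-scale tissue shapes do not need
# sub-micron sampling; masks at the working resolutions are derived by
# nearest-neighbour resampling in the shared micron frame
GEOM_MPP <- 2

#' Generate a synthetic tissue layout
#'
#' Builds the class geometry (background / normal / tumour / stroma /
#' necrosis) and returns the broad cancer mask at 4 MPP, the
#' tumour/stroma/necrosis mask at 0.5 MPP, and the internal geometry used
#' by [slide_source()] to render RGB tiles on demand. The TSN partition is
#' cut from a smooth random field by within-cancer quantiles, so realised
#' class fractions track the requested ones closely.
#'
#' @param spec A [layout_spec()].
#' @return A `synthetic_layout`: list with `broad` ([label_raster()] at
#'   4 MPP, classes other/cancer), `tsn` ([label_raster()] at 0.5 MPP,
#'   classes other/tumour/stroma/necrosis), `geometry` (internal class grid)
#'   and `spec`.
#' @export
generate_layout <- function(spec = layout_spec()) {
  with_seed(spec$seed, {
    w <- max(2L, as.integer(round(spec$extent_um[1] / GEOM_MPP)))
    h <- max(2L, as.integer(round(spec$extent_um[2] / GEOM_MPP)))
    xc <- (seq_len(w) - 0.5) * GEOM_MPP
    yc <- (seq_len(h) - 0.5) * GEOM_MPP
    X <- matrix(xc, h, w, byrow = TRUE)
    Y <- matrix(yc, h, w)

    cancer <- matrix(FALSE, h, w)
    tissue <- matrix(FALSE, h, w)
    for (b in seq_len(spec$n_blobs)) {
      cxy <- spec$extent_um * stats::runif(2, 0.25, 0.75)
      r0 <- min(spec$extent_um) * stats::runif(1, 0.22, 0.34)
      ph <- stats::runif(3, 0, 2 * pi)
      a <- c(0.22, 0.13, 0.07) * stats::runif(3, 0.6, 1.4)
      dx <- X - cxy[1]; dy <- Y - cxy[2]
      rr <- sqrt(dx^2 + dy^2)
      th <- atan2(dy, dx)
      rad <- r0 * (1 + a[1] * cos(2 * th + ph[1]) + a[2] * cos(3 * th + ph[2]) +
                     a[3] * cos(5 * th + ph[3]))
      cancer <- cancer | (rr < rad)
      tissue <- tissue | (rr < 1.22 * rad)   # normal-tissue rim
    }

    # smooth low-frequency field; within-cancer quantile cuts give the
    # requested tumour/stroma/necrosis fractions up to pixel ties
    u <- matrix(0, h, w)
    for (j in 1:8) {
      f <- stats::runif(2, -1, 1) / stats::runif(1, 450, 900)
      u <- u + stats::runif(1, 0.5, 1) * cos(2 * pi * (f[1] * X + f[2] * Y) +
                                               stats::runif(1, 0, 2 * pi))
    }

    grid <- matrix(1L, h, w)                       # background
    grid[tissue] <- 2L                             # normal
    if (any(cancer)) {
      qs <- stats::quantile(u[cancer],
                            cumsum(spec$tsn_fractions)[1:2], names = FALSE)
      grid[cancer] <- 4L                           # stroma
      grid[cancer & u <= qs[1]] <- 3L              # tumour
      grid[cancer & u > qs[2]] <- 5L               # necrosis
    }

    geometry <- label_raster(grid, c("background", "normal", "tumour",
                                     "stroma", "necrosis"), GEOM_MPP)
    broad_grid <- resample_label(geometry, 4)
    broad <- label_raster(ifelse(broad_grid$grid >= 3L, 2L, 1L),
                          c("other", "cancer"), 4)
    tsn_geom <- resample_label(geometry, 0.5)
    tsn_map <- c(1L, 1L, 2L, 3L, 4L)               # background/normal -> other
    tsn <- label_raster(matrix(tsn_map[tsn_geom$grid], nrow(tsn_geom$grid)),
                        c("other", "tumour", "stroma", "necrosis"), 0.5)

    structure(list(broad = broad, tsn = tsn, geometry = geometry, spec = spec),
              class = "synthetic_layout")
  })
}

#' Planted TIL point-process specification
#'
#' @param lambda_tumour iTIL intensity per mm^2 of tumour.
#' @param lambda_stroma TIL intensity per mm^2 of stroma.
#' @param min_separation_um Hard-core separation between planted TILs
#'   (default 6, so the codec's recovery assumptions hold by construction).
#' @param seed Integer seed.
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(lambda_tumour = 17, lambda_stroma = 40,
                       min_separation_um = 6, seed = 1) {
  if (lambda_tumour < 0 || lambda_stroma < 0) {
    itil_error("itil_invalid_argument", "intensities must be nonnegative")
  }
  list(lambda_tumour = lambda_tumour, lambda_stroma = lambda_stroma,
       min_separation_um = min_separation_um, seed = as.integer(seed))
}

# rejection-sample n uniform points on pixels of class `cls`
sample_points_in_class <- function(mask, cls, n) {
  if (n == 0) return(data.frame(x_um = numeric(), y_um = numeric()))
  ext <- raster_extent_um(mask)
  frac <- class_area_mm2(mask, cls) / (ext[1] * ext[2] / 1e6)
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < n) {
    m <- ceiling(1.4 * (n - length(xs)) / max(frac, 1e-6)) + 16
    cx <- stats::runif(m, 0, ext[1]) + mask$origin_um[1]
    cy <- stats::runif(m, 0, ext[2]) + mask$origin_um[2]
    keep <- raster_class_at(mask, cx, cy) %in% cls
    xs <- c(xs, cx[keep]); ys <- c(ys, cy[keep])
  }
  data.frame(x_um = xs[seq_len(n)], y_um = ys[seq_len(n)])
}

#' Plant a TIL point process on a tissue mask
#'
#' Homogeneous Poisson process per compartment (tumour and stroma), thinned
#' to a hard-core minimum separation (Matern-style: points are visited in
#' random order and dropped when within `min_separation_um` of a kept
#' point). Ground-truth compartment labels are attached.
#'
#' @param tsn_mask A [label_raster()] with classes including tumour/stroma.
#' @param spec A [plant_spec()].
#' @return A ground-truth [point_set()] (confidence 1).
#' @export
plant_tils <- function(tsn_mask, spec = plant_spec()) {
  with_seed(spec$seed, {
    parts <- list()
    for (comp in c("tumour", "stroma")) {
      lam <- if (comp == "tumour") spec$lambda_tumour else spec$lambda_stroma
      if (lam <= 0 || !(comp %in% tsn_mask$classes)) next
      a <- class_area_mm2(tsn_mask, comp)
      n <- stats::rpois(1, lam * a)
      if (n == 0) next
      pts <- sample_points_in_class(tsn_mask, comp, n)
      pts$compartment <- comp
      parts[[comp]] <- pts
    }
    if (length(parts) == 0) return(point_set())
    all <- do.call(rbind, parts)
    n_all <- nrow(all)
    # hard-core thinning in random visiting order
    ord_conf <- stats::runif(n_all)
    thinned <- point_nms(point_set(all$x_um, all$y_um, confidence = ord_conf,
                                   compartment = all$compartment),
                         spec$min_separation_um)
    if (nrow(thinned) < 0.5 * n_all) {
      warning("hard-core thinning removed more than half the drawn points; ",
              "intensity is near saturation for this min_separation_um")
    }
    thinned$confidence <- 1
    ord <- order(thinned$y_um, thinned$x_um)
    out <- thinned[ord, , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("point_set", "data.frame")
    out
  })
}

#' Lazy tile renderer for a synthetic slide
#'
#' Wraps a [generate_layout()] result (plus optional planted TILs) as a
#' renderer that can produce any pixel window at any of the working
#' resolutions, the way whole-slide images are accessed in practice.
#' Tissue classes are painted with the [toy_palette()] colours plus a
#' deterministic per-pixel jitter (a hash of global pixel coordinates and
#' the seed, so overlapping tiles agree bit-exactly); TIL markers are
#' painted as disks of radius `til_radius_um` at the detection resolution
#' only, keeping segmentation-resolution colours unambiguous.
#'
#' @param layout A `synthetic_layout` from [generate_layout()].
#' @param tils Optional planted [point_set()] from [plant_tils()].
#' @param til_radius_um Rendered TIL disk radius (default 3).
#' @param jitter Peak colour jitter amplitude (default 3 intensity levels).
#' @return A `slide_source`: list with `extent_um` and
#'   `render(x0_px, y0_px, w_px, h_px, mpp)`.
#' @export
slide_source <- function(layout, tils = point_set(), til_radius_um = 3,
                         jitter = 3) {
  geom <- layout$geometry
  palette <- toy_palette()
  seed <- layout$spec$seed
  extent_um <- layout$spec$extent_um

  render <- function(x0_px, y0_px, w_px, h_px, mpp) {
    ix <- x0_px + seq_len(w_px) - 1L
    iy <- y0_px + seq_len(h_px) - 1L
    cx <- (ix + 0.5) * mpp
    cy <- (iy + 0.5) * mpp
    gx <- pmin(ncol(geom$grid) - 1L, pmax(0L, floor(cx / geom$mpp)))
    gy <- pmin(nrow(geom$grid) - 1L, pmax(0L, floor(cy / geom$mpp)))
    cls <- geom$grid[gy + 1L, gx + 1L, drop = FALSE]
    out <- array(0, c(h_px, w_px, 3))
    IX <- matrix(ix, h_px, w_px, byrow = TRUE)
    IY <- matrix(iy, h_px, w_px)
    jit <- (pixel_hash(IX, IY, seed) - 3) * (jitter / 3)  # shared luminance jitter
    for (ch in 1:3) {
      col <- palette[cls, ch]
      dim(col) <- dim(cls)
      out[, , ch] <- col + jit
    }
    if (mpp <= 0.3 && nrow(tils) > 0) {
      r_um <- til_radius_um
      win_x <- c(min(cx), max(cx)); win_y <- c(min(cy), max(cy))
      sel <- tils$x_um >= win_x[1] - r_um - mpp & tils$x_um <= win_x[2] + r_um + mpp &
        tils$y_um >= win_y[1] - r_um - mpp & tils$y_um <= win_y[2] + r_um + mpp
      for (i in which(sel)) {
        lx <- tils$x_um[i] / mpp - x0_px - 0.5    # local pixel-centre coords
        ly <- tils$y_um[i] / mpp - y0_px - 0.5
        r_px <- r_um / mpp
        jx0 <- max(1, ceiling(lx - r_px + 1)); jx1 <- min(w_px, floor(lx + r_px + 1))
        jy0 <- max(1, ceiling(ly - r_px + 1)); jy1 <- min(h_px, floor(ly + r_px + 1))
        if (jx1 < jx0 || jy1 < jy0) next
        jx <- jx0:jx1
        jy <- jy0:jy1
        inside <- outer((jy - 1 - ly)^2, (jx - 1 - lx)^2, "+") <= r_px^2
        for (ch in 1:3) {
          sub <- out[jy, jx, ch, drop = FALSE]
          sub[inside] <- palette["til", ch]
          out[jy, jx, ch] <- sub
        }
      }
    }
    pmin(pmax(out, 0), 255)
  }

  structure(list(extent_um = extent_um, render = render,
                 til_radius_um = til_radius_um),
            class = "slide_source")
}

#' Render a synthetic model-output heatmap
#'
#' Simulates what the TIL detector emits: planted points rendered as
#' Gaussians with peaks in `peak_range`, plus optional low-amplitude decoy
#' blobs (below the confidence gate) and additive noise.
#'
#' @param points True [point_set()] in microns.
#' @param spec A [heatmap_spec()].
#' @param extent_px Heatmap extent `(width, height)` in pixels.
#' @param peak_range Peak range for true points (default `c(0.6, 1)`).
#' @param n_decoys Number of spurious faint blobs (default 0).
#' @param decoy_peak_range Peak range for decoys (default `c(0.05, 0.30)`,
#'   below the 0.35 gate).
#' @param noise_sd Additive Gaussian noise sd (default 0, at most ~0.02
#'   sensible).
#' @param seed Integer seed.
#' @param origin_um Micron offset of heatmap pixel (0, 0).
#' @return Numeric heatmap matrix in [0, 1].
#' @export
render_heatmap <- function(points, spec = heatmap_spec(), extent_px,
                           peak_range = c(0.6, 1.0), n_decoys = 0,
                           decoy_peak_range = c(0.05, 0.30), noise_sd = 0,
                           seed = 1, origin_um = c(0, 0)) {
  with_seed(seed, {
    heat <- matrix(0, extent_px[2], extent_px[1])
    sigma_px <- spec$sigma_um / spec$mpp
    if (nrow(points) > 0) {
      amps <- stats::runif(nrow(points), peak_range[1], peak_range[2])
      px <- floor((points$x_um - origin_um[1]) / spec$mpp)
      py <- floor((points$y_um - origin_um[2]) / spec$mpp)
      for (i in seq_len(nrow(points))) {
        heat <- gauss_paint(heat, px[i], py[i], sigma_px, amps[i])
      }
    }
    if (n_decoys > 0) {
      dx <- floor(stats::runif(n_decoys, 0, extent_px[1]))
      dy <- floor(stats::runif(n_decoys, 0, extent_px[2]))
      da <- stats::runif(n_decoys, decoy_peak_range[1], decoy_peak_range[2])
      for (i in seq_len(n_decoys)) {
        heat <- gauss_paint(heat, dx[i], dy[i], sigma_px, da[i])
      }
    }
    if (noise_sd > 0) {
      heat <- heat + matrix(stats::rnorm(length(heat), 0, noise_sd),
                            nrow(heat))
    }
    pmin(pmax(heat, 0), 1)
  })
}

#' Synthetic survival-cohort specification
#'
#' Patients receive a log-normal AI iTIL score; the event hazard is
#' exponential with a step at the planted cut-off (hazard multiplied by
#' `hazard_ratio` for scores below it), with independent uniform censoring.
#' Defaults give roughly two-thirds events within follow-up, a balanced
#' High/Low split at 17, and clinicopathological covariates with realistic
#' prevalences.
#'
#' @param n_patients Number of patients (>= 2).
#' @param true_cutoff Planted risk cut-off on the score scale (default 17).
#' @param hazard_ratio Hazard multiplier for TIL-Low vs TIL-High (> 0,
#'   default 2).
#' @param baseline_hazard Daily event hazard for TIL-High (default 5.5e-4).
#' @param censor_max_days Upper bound of uniform censoring (default 3650).
#' @param score_meanlog,score_sdlog Log-normal score parameters (defaults
#'   `log(17)` and 0.7, centring the score distribution on the cut-off).
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 400, true_cutoff = 17, hazard_ratio = 2,
                        baseline_hazard = 5.5e-4, censor_max_days = 3650,
                        score_meanlog = log(17), score_sdlog = 0.7, seed = 1) {
  if (n_patients < 2) itil_error("itil_invalid_argument", "n_patients must be >= 2")
  if (hazard_ratio <= 0) itil_error("itil_invalid_argument", "hazard_ratio must be > 0")
  list(n_patients = as.integer(n_patients), true_cutoff = true_cutoff,
       hazard_ratio = hazard_ratio, baseline_hazard = baseline_hazard,
       censor_max_days = censor_max_days, score_meanlog = score_meanlog,
       score_sdlog = score_sdlog, seed = as.integer(seed))
}

#' Generate a synthetic survival cohort
#'
#' @param spec A [cohort_spec()].
#' @return A `cohort_table` data frame with per-patient id, survival time
#'   (days), event indicator, stage and covariates, AI iTIL score and TIL
#'   class (at the planted cut-off). Five-year truncation is applied
#'   downstream via [censor_at_5_years()].
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  with_seed(spec$seed, {
    n <- spec$n_patients
    score <- stats::rlnorm(n, spec$score_meanlog, spec$score_sdlog)
    low <- score < spec$true_cutoff
    hazard <- spec$baseline_hazard * ifelse(low, spec$hazard_ratio, 1)
    t_event <- stats::rexp(n, hazard)
    t_cens <- stats::runif(n, 1, spec$censor_max_days)
    tab <- data.frame(
      id = sprintf("P%04d", seq_len(n)),
      time_days = pmax(1, round(pmin(t_event, t_cens))),
      event = as.integer(t_event <= t_cens),
      endpoint = "RFS",
      stage = sample(c("II", "III"), n, replace = TRUE, prob = c(0.45, 0.55)),
      age_decades = round(stats::rnorm(n, 6.9, 1.2), 1),
      gender = sample(c("female", "male"), n, replace = TRUE),
      site = sample(c("proximal", "distal"), n, replace = TRUE),
      t4 = stats::rbinom(n, 1, 0.25) == 1,
      n2 = stats::rbinom(n, 1, 0.30) == 1,
      nodes_lt12 = stats::rbinom(n, 1, 0.20) == 1,
      grade_high = stats::rbinom(n, 1, 0.25) == 1,
      lvi = stats::rbinom(n, 1, 0.30) == 1,
      emvi = stats::rbinom(n, 1, 0.20) == 1,
      mmr_deficient = stats::rbinom(n, 1, 0.15) == 1,
      adjuvant_chemo = stats::rbinom(n, 1, 0.5) == 1,
      ai_itil_score = score,
      stringsAsFactors = FALSE
    )
    tab$til_class <- classify(tab$ai_itil_score, spec$true_cutoff)
    class(tab) <- c("cohort_table", "data.frame")
    tab
  })
}
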