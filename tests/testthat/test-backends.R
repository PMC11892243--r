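test_that("toy broad segmentation recovers the generated cancer mask", {
  sc <- small_scene()
  broad <- run_broad_segmentation(sc$source)
  expect_s3_class(broad, "label_raster")
  expect_gte(segmentation_f1(broad, sc$layout$broad, "cancer"), 0.99)

  # reconstruction conserves area: slide mask area equals summed tile areas
  plan <- plan_tiles(raster_extent_px(broad), 512, 0, mpp = 4)
  tiles <- split_raster(broad, plan)
  tile_px <- sum(vapply(tiles, function(t) sum(t == 2L), numeric(1)))
  expect_equal(class_area_mm2(broad, "cancer"), tile_px * (4 / 1000)^2)
})

test_that("a blank slide segments as entirely non-cancerous", {
  blank <- rgb_raster(array(242, c(256, 256, 3)), 0.25)
  broad <- run_broad_segmentation(blank)
  expect_true(all(broad$grid == raster_class_id(broad, "other")))

  tsn <- run_tsn_segmentation(blank, broad)
  expect_true(all(tsn$grid == raster_class_id(tsn, "other")))
  expect_equal(class_area_mm2(tsn, "tumour"), 0)
})

test_that("TSN segmentation is restricted to broadly cancerous tissue", {
  # slide painted entirely in tumour colour
  lab <- rect_raster(256, 256, 0.5, fill = 2L)
  slide <- palette_rgb_raster(lab, c(other = "background", tumour = "tumour"))
  slide$mpp <- 0.5

  # broad mask that calls everything 'other': no tumour may survive
  broad_other <- label_raster(matrix(1L, 32, 32), c("other", "cancer"), 4)
  tsn <- run_tsn_segmentation(slide, broad_other)
  expect_equal(class_area_mm2(tsn, "tumour"), 0)

  # broad mask that calls everything cancer: the tumour is kept intact
  broad_cancer <- label_raster(matrix(2L, 32, 32), c("other", "cancer"), 4)
  tsn2 <- run_tsn_segmentation(slide, broad_cancer)
  expect_equal(sum(tsn2$grid == raster_class_id(tsn2, "tumour")), 256 * 256)

  shifted <- label_raster(matrix(2L, 32, 32), c("other", "cancer"), 4,
                          origin_um = c(10, 0))
  expect_error(run_tsn_segmentation(slide, shifted),
               class = "itil_invalid_argument")
})

test_that("toy TSN segmentation matches the generated compartments", {
  sc <- small_scene()
  broad <- run_broad_segmentation(sc$source)
  tsn <- run_tsn_segmentation(sc$source, broad)
  for (cls in c("tumour", "stroma", "necrosis")) {
    expect_gte(segmentation_f1(tsn, sc$layout$tsn, cls), 0.99)
  }
  # nearest-neighbour cross-resolution resampling preserves class areas
  up <- resample_label(broad, 0.5)
  expect_lt(abs(class_area_mm2(up, "cancer") / class_area_mm2(broad, "cancer") - 1),
            0.01)
})

test_that("TIL detection recovers planted points inside cancer and drops the rest", {
  sc <- small_scene()
  broad <- run_broad_segmentation(sc$source)
  pts <- run_til_detection(sc$source, broad)
  expect_equal(nrow(pts), nrow(sc$tils))
  m <- match_points(pts, sc$tils, eval_config(match_radius_um = 0.5))
  expect_equal(m$tp, nrow(sc$tils))   # within 2 px at 0.25 MPP

  # stage restriction: no detection outside the broad cancer mask
  expect_true(all(raster_class_at(broad, pts$x_um, pts$y_um) == "cancer"))

  # TILs rendered outside cancer (in the normal rim) are excluded
  lay <- sc$layout
  g <- lay$geometry$grid
  normal_px <- which(g == 2L, arr.ind = TRUE)
  interior <- NULL
  for (k in seq_len(nrow(normal_px))) {   # pick one well inside the rim
    r <- normal_px[k, 1]; c <- normal_px[k, 2]
    if (r > 4 && c > 4 && r < nrow(g) - 4 && c < ncol(g) - 4 &&
        all(g[(r - 4):(r + 4), (c - 4):(c + 4)] == 2L)) {
      interior <- c(r, c); break
    }
  }
  expect_false(is.null(interior))
  outside <- point_set((interior[2] - 0.5) * 2, (interior[1] - 0.5) * 2)
  src2 <- slide_source(lay, outside)
  pts2 <- run_til_detection(src2, broad)
  expect_equal(nrow(pts2), 0)
})

test_that("a slide with no TILs yields an empty detection set", {
  sc <- small_scene()
  src <- slide_source(sc$layout, point_set())
  broad <- run_broad_segmentation(src)
  expect_equal(nrow(run_til_detection(src, broad)), 0)
})

test_that("toy backends and the renderer are deterministic", {
  lay1 <- generate_layout(layout_spec(extent_um = c(600, 600), seed = 5))
  lay2 <- generate_layout(layout_spec(extent_um = c(600, 600), seed = 5))
  expect_identical(lay1$broad$grid, lay2$broad$grid)
  expect_identical(lay1$tsn$grid, lay2$tsn$grid)

  src1 <- slide_source(lay1)
  src2 <- slide_source(lay2)
  t1 <- src1$render(100, 100, 64, 64, 0.25)
  t2 <- src2$render(100, 100, 64, 64, 0.25)
  expect_identical(t1, t2)

  # overlapping windows agree bit-exactly on shared pixels
  a <- src1$render(0, 0, 64, 64, 0.25)
  b <- src1$render(32, 0, 64, 64, 0.25)
  expect_identical(a[, 33:64, ], b[, 1:32, ])

  be <- get_backend("broad", "toy")
  expect_identical(be$predict(t1, 4), be$predict(t1, 4))
})

test_that("any contract-satisfying backend yields a valid slide score", {
  # deterministic pseudo-random backend: probabilities from a fixed pattern
  noisy_broad <- backend_spec("broad", "noise", function(rgb, mpp) {
    h <- nrow(rgb); w <- ncol(rgb)
    p <- (outer(seq_len(h), seq_len(w), function(i, j) (i * 7 + j * 3) %% 11)) / 11
    array(c(1 - p, p), c(h, w, 2))
  }, classes = c("other", "cancer"))
  noisy_tsn <- backend_spec("tsn", "noise", function(rgb, mpp) {
    h <- nrow(rgb); w <- ncol(rgb)
    p <- (outer(seq_len(h), seq_len(w), function(i, j) (i * 5 + j) %% 7)) / 7
    array(c(p, 1 - p, p / 2, p / 3), c(h, w, 4))
  }, classes = c("other", "tumour", "stroma", "necrosis"))
  noisy_til <- backend_spec("til", "noise", function(rgb, mpp) {
    h <- nrow(rgb); w <- ncol(rgb)
    outer(seq_len(h), seq_len(w), function(i, j) ((i * 13 + j * 29) %% 97) / 97)
  })
  slide <- rgb_raster(array(150, c(512, 512, 3)), 0.25)
  ss <- score_slide(slide, "noise-slide",
                    backends = list(broad = noisy_broad, tsn = noisy_tsn,
                                    til = noisy_til))
  expect_s3_class(ss, "slide_score")
  expect_true(is.data.frame(ss$fields))
  expect_true(all(c("T_mm2", "L", "density", "eligible") %in% names(ss$fields)))
  expect_s3_class(ss$flags, "flag_report")
  # stage restriction holds even for arbitrary backends
  if (nrow(ss$points) > 0) {
    broad <- run_broad_segmentation(slide, noisy_broad)
    expect_true(all(raster_class_at(broad, ss$points$x_um, ss$points$y_um) == "cancer"))
  }
})

test_that("backend failures surface with the failing tile index", {
  bad <- backend_spec("broad", "bad", function(rgb, mpp) stop("boom"),
                      classes = c("other", "cancer"))
  slide <- rgb_raster(array(150, c(64, 64, 3)), 4)
  expect_error(run_broad_segmentation(slide, bad),
               class = "itil_backend_failure", regexp = "tile 1")
  expect_error(get_backend("broad", "unregistered"),
               class = "itil_invalid_argument")
})

test_that("per-tile stain failures are counted and do not stop the pipeline", {
  # an all-white slide fails Macenko on every tile but still segments
  blank <- rgb_raster(array(255, c(256, 256, 3)), 2)
  broad <- run_broad_segmentation(blank, normalise_stains = TRUE)
  expect_equal(attr(broad, "stain_failures"), 1L)   # one 128 px extent tile
  expect_true(all(broad$grid == raster_class_id(broad, "other")))

  rep <- flag_slide(list(stain_failures = attr(broad, "stain_failures")),
                    flag_criteria())
  expect_true(rep$flagged)
  expect_equal(rep$criteria_triggered$criterion, "stain-failure")
})
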