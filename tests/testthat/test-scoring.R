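test_that("compartment assignment looks points up in the TSN mask", {
  mask <- rect_raster(100, 100, 0.5,
                      classes = c("other", "tumour", "stroma", "necrosis"),
                      fill = 3L, rect = c(0, 0, 50, 100), rect_class = 2L)
  # x < 25 um is tumour, the rest stroma
  pts <- point_set(c(10, 40, 200), c(10, 10, 10))
  out <- assign_compartment(pts, mask)
  expect_equal(out$compartment, c("tumour", "stroma", "unassigned"))

  # necrosis points are recorded but never scored
  nmask <- rect_raster(20, 20, 0.5,
                       classes = c("other", "tumour", "stroma", "necrosis"),
                       fill = 4L)
  np <- assign_compartment(point_set(5, 5), nmask)
  expect_equal(np$compartment, "necrosis")
  f <- score_field(list(index = 1L, x0 = 0, y0 = 0, x1 = 10, y1 = 10),
                   nmask, np, scoring_config())
  expect_equal(f$L, 0L)

  # agreement with a brute-force per-point pixel lookup
  set.seed(31)
  g <- matrix(sample(1:4, 60 * 60, replace = TRUE), 60, 60)
  m <- label_raster(g, c("other", "tumour", "stroma", "necrosis"), 0.5)
  xs <- runif(1000, 0, 30); ys <- runif(1000, 0, 30)
  got <- assign_compartment(point_set(xs, ys), m)$compartment
  want <- character(1000)
  for (i in 1:1000) {
    cls <- m$classes[g[floor(ys[i] / 0.5) + 1, floor(xs[i] / 0.5) + 1]]
    want[i] <- if (cls == "other") "unassigned" else cls
  }
  expect_equal(got, want)
})

test_that("the field grid snaps to whole pixels and covers the tumour bbox", {
  cfg <- scoring_config()
  expect_equal(cfg$field_side_um, 1000 * 0.275 * sqrt(pi))
  expect_equal(cfg$field_side_um^2 / 1e6, cfg$field_area_mm2, tolerance = 1e-12)

  # 975 x 975 px tumour bbox at 0.5 MPP -> a single field
  m1 <- rect_raster(1000, 1000, 0.5, rect = c(10, 10, 985, 985))
  g1 <- build_field_grid(m1, cfg)
  expect_equal(nrow(g1), 1)
  expect_equal(g1$x1 - g1$x0, 487.5)   # 975 px * 0.5 um

  # bbox twice the side in each dimension -> 2 x 2
  m2 <- rect_raster(2000, 2000, 0.5, rect = c(0, 0, 1950, 1950))
  expect_equal(nrow(build_field_grid(m2, cfg)), 4)

  empty <- rect_raster(100, 100, 0.5)
  expect_equal(nrow(build_field_grid(empty, cfg)), 0)
})

test_that("field scoring counts iTILs per tumour area with the 10% eligibility rule", {
  cfg <- scoring_config()
  side <- 975 * 0.5
  full <- rect_raster(975, 975, 0.5, fill = 2L)
  pts <- assign_compartment(point_set(runif(10, 0, side), runif(10, 0, side),
                                      confidence = 1), full)
  f <- score_field(list(index = 1L, x0 = 0, y0 = 0, x1 = side, y1 = side),
                   full, pts, cfg)
  expect_equal(f$T_mm2, 975^2 * (0.5 / 1000)^2)
  expect_equal(f$L, 10L)
  expect_equal(f$density, 10 / f$T_mm2)
  expect_equal(f$density, 42.09, tolerance = 0.002)   # ~10 / (pi * 0.275^2)
  expect_true(f$eligible)

  # 5% tumour -> ineligible; zero iTILs in an eligible field -> density 0
  sparse <- rect_raster(975, 975, 0.5, rect = c(0, 0, 218, 218))  # ~5%
  fs <- score_field(list(index = 1L, x0 = 0, y0 = 0, x1 = side, y1 = side),
                    sparse, pts[0, ], cfg)
  expect_false(fs$eligible)
  half <- rect_raster(975, 975, 0.5, rect = c(0, 0, 975, 487))
  fh <- score_field(list(index = 1L, x0 = 0, y0 = 0, x1 = side, y1 = side),
                    half, pts[0, ], cfg)
  expect_true(fh$eligible)
  expect_equal(fh$density, 0)
})

test_that("field scoring matches a brute-force pixel/point oracle", {
  set.seed(32)
  cfg <- scoring_config(min_tumour_frac = 0.1)
  for (i in 1:100) {
    w <- sample(30:80, 1); h <- sample(30:80, 1); mpp <- sample(c(0.5, 1, 2), 1)
    g <- matrix(sample(1:2, w * h, replace = TRUE), h, w)
    m <- label_raster(g, c("other", "tumour"), mpp)
    n <- sample(0:30, 1)
    pts <- point_set(runif(n, 0, w * mpp), runif(n, 0, h * mpp),
                     compartment = sample(c("tumour", "stroma"), n, replace = TRUE))
    fx <- sort(runif(2, 0, w * mpp)); fy <- sort(runif(2, 0, h * mpp))
    fx <- round(fx / mpp) * mpp; fy <- round(fy / mpp) * mpp
    if (diff(fx) == 0 || diff(fy) == 0) next
    field <- list(index = 1L, x0 = fx[1], y0 = fy[1], x1 = fx[2], y1 = fy[2])
    got <- score_field(field, m, pts, cfg)

    t_brute <- 0L
    for (r in seq_len(h)) for (cc in seq_len(w)) {
      px <- (cc - 1) * mpp; py <- (r - 1) * mpp    # top-left corner of pixel
      if (g[r, cc] == 2L && px >= fx[1] && px < fx[2] && py >= fy[1] && py < fy[2]) {
        t_brute <- t_brute + 1L
      }
    }
    l_brute <- 0L
    for (k in seq_len(n)) {
      if (pts$compartment[k] == "tumour" &&
          pts$x_um[k] >= fx[1] && pts$x_um[k] < fx[2] &&
          pts$y_um[k] >= fy[1] && pts$y_um[k] < fy[2]) l_brute <- l_brute + 1L
    }
    expect_equal(got$T_mm2, t_brute * (mpp / 1000)^2)
    expect_equal(got$L, l_brute)
  }
})

test_that("grid fields conserve the total in-grid tumour point count", {
  set.seed(33)
  m <- rect_raster(600, 500, 1, rect = c(20, 30, 580, 470))
  cfg <- scoring_config(hpf_diameter_mm = 0.2)   # small fields -> several rows
  grid <- build_field_grid(m, cfg)
  expect_gt(nrow(grid), 4)
  pts <- point_set(runif(300, 0, 600), runif(300, 0, 500),
                   compartment = "tumour")
  fields <- score_fields(grid, m, pts, cfg)
  x0 <- min(grid$x0); x1 <- max(grid$x1); y0 <- min(grid$y0); y1 <- max(grid$y1)
  in_grid <- sum(pts$x_um >= x0 & pts$x_um < x1 & pts$y_um >= y0 & pts$y_um < y1)
  expect_equal(sum(fields$L), in_grid)
})

test_that("the patient score is the pooled median and is invariant to slide splits", {
  mk <- function(d) list(fields = data.frame(density = d,
                                             eligible = TRUE,
                                             T_mm2 = 1, L = 1))
  expect_equal(ai_itil_score(list(mk(c(10, 20, 30))))$ai_itil_score, 20)
  expect_equal(ai_itil_score(list(mk(c(10, 20))))$ai_itil_score, 15)

  set.seed(34)
  d <- runif(21, 0, 60)
  whole <- ai_itil_score(list(mk(d)))$ai_itil_score
  expect_equal(ai_itil_score(list(mk(d[1:7]), mk(d[8:21])))$ai_itil_score, whole)
  expect_equal(ai_itil_score(list(mk(sample(d))))$ai_itil_score, whole)

  # ineligible fields never contribute
  s <- list(fields = data.frame(density = c(5, 500), eligible = c(TRUE, FALSE),
                                T_mm2 = 1, L = 1))
  expect_equal(ai_itil_score(list(s))$ai_itil_score, 5)

  none <- ai_itil_score(list(list(fields = data.frame(density = numeric(),
                                                      eligible = logical(),
                                                      T_mm2 = numeric(),
                                                      L = integer()))))
  expect_true(none$undefined)
  expect_true(is.na(none$ai_itil_score))
})

test_that("adding an iTIL inside an eligible field never lowers the score", {
  set.seed(35)
  m <- rect_raster(300, 300, 1, fill = 2L)
  cfg <- scoring_config(hpf_diameter_mm = 0.1)
  grid <- build_field_grid(m, cfg)
  pts <- point_set(runif(40, 0, 300), runif(40, 0, 300), compartment = "tumour")
  base <- ai_itil_score(list(list(fields = score_fields(grid, m, pts, cfg))), cfg)
  for (i in 1:5) {
    extra <- point_set(runif(1, 0, 300), runif(1, 0, 300), compartment = "tumour")
    pts2 <- rbind(pts, extra); class(pts2) <- class(pts)
    s2 <- ai_itil_score(list(list(fields = score_fields(grid, m, pts2, cfg))), cfg)
    expect_gte(s2$ai_itil_score, base$ai_itil_score)
  }
})

test_that("classification thresholds the score at 17 with High on the boundary", {
  expect_equal(classify(17.0), "TIL-High")
  expect_equal(classify(16.9), "TIL-Low")
  expect_equal(classify(42.09), "TIL-High")
  expect_equal(classify(c(5, 60), cutoff = 17), c("TIL-Low", "TIL-High"))
  expect_error(classify(NaN), class = "itil_invalid_argument")
})

test_that("HPF equivalence converts per-field counts to per-mm2 densities", {
  expect_equal(round(hpf_equivalent_density(2, 0.5, 0.55)), 17)
  expect_equal(hpf_equivalent_density(2, 0.5, 0.55), 16.84, tolerance = 0.001)
  expect_equal(round(hpf_equivalent_density(2, 0.6, 0.55)), 14)
  expect_equal(round(hpf_equivalent_density(2, 0.4, 0.55)), 21)
  expect_equal(hpf_equivalent_density(0, 0.3, 0.55), 0)
  expect_error(hpf_equivalent_density(2, 0, 0.55), class = "itil_invalid_argument")
})

test_that("the manual five-HPF rule averages counts against the 2/HPF cut-off", {
  expect_equal(manual_score_classify(c(2, 2, 2, 2, 2)), "TIL-High")
  expect_equal(manual_score_classify(c(1, 1, 1, 1, 1)), "TIL-Low")
  expect_equal(manual_score_classify(c(0, 0, 0, 5, 5)), "TIL-High")   # mean 2
  expect_error(manual_score_classify(numeric()), class = "itil_invalid_argument")
  expect_error(manual_score_classify(c(1, 2)), class = "itil_invalid_argument")
})

test_that("flagging criteria trigger independently and report measured values", {
  crit <- flag_criteria()
  f1 <- flag_slide(list(tumour_area_mm2 = 0.2), crit)
  expect_true(f1$flagged)
  expect_equal(f1$criteria_triggered$criterion, "insufficient-tumour")
  expect_equal(f1$criteria_triggered$value, 0.2)

  f2 <- flag_slide(list(eligible_field_count = 3), crit)
  expect_equal(f2$criteria_triggered$criterion, "too-few-fields")

  f3 <- flag_slide(list(tumour_area_mm2 = 5, eligible_field_count = 40,
                        cancer_fraction_of_tissue = 0.6, stain_failures = 0), crit)
  expect_false(f3$flagged)
  expect_equal(nrow(f3$criteria_triggered), 0)

  f4 <- flag_slide(list(cancer_fraction_of_tissue = 0.01, stain_failures = 2), crit)
  expect_setequal(f4$criteria_triggered$criterion,
                  c("low-cancer-fraction", "stain-failure"))
})

test_that("cohort summaries report flag rates to one decimal", {
  mk <- function(nf, nr) data.frame(flagged = rep(c(TRUE, FALSE), c(nf, nr)))
  expect_equal(summarize_cohort(mk(38, 1070))$flag_rate_pct, 3.4)
  expect_equal(summarize_cohort(mk(53, 885))$flag_rate_pct, 5.7)
  expect_equal(summarize_cohort(mk(35, 353))$flag_rate_pct, 9.0)
  expect_equal(summarize_cohort(mk(0, 10))$flag_rate_pct, 0.0)
  s <- summarize_cohort(data.frame(flagged = c(TRUE, FALSE, FALSE),
                                   til_class = c("TIL-Low", "TIL-High", "TIL-Low"),
                                   ai_itil_score = c(3, 40, 9)))
  expect_equal(s$n_retained, 2)
  expect_equal(unname(s$til_class_counts["TIL-High"]), 1)
})

test_that("a planted uniform density is recovered by the median of field densities", {
  # direct scoring-path check at a density where the integer-count
  # granularity is negligible (lambda * T >> 1)
  set.seed(36)
  lam <- 60
  m <- rect_raster(1950, 1950, 1, fill = 2L)   # 3.8 mm2, all tumour
  cfg <- scoring_config()
  grid <- build_field_grid(m, cfg)
  expect_gte(nrow(grid), 16)
  n <- rpois(1, lam * class_area_mm2(m, "tumour"))
  pts <- point_set(runif(n, 0, 1950), runif(n, 0, 1950), compartment = "tumour")
  fields <- score_fields(grid, m, pts, cfg)
  ps <- ai_itil_score(list(list(fields = fields)), cfg)
  expect_lt(abs(ps$ai_itil_score / lam - 1), 0.1)
})
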