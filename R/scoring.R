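#' iTIL scoring configuration
#'
#' Parameters of the high-power-field-equivalent scoring scheme. The manual
#' criterion this mirrors enumerates iTILs in five circular high-power
#' fields (HPFs) of diameter 0.55 mm; the automated score uses square
#' fields of the same area (side `1000 * (d/2) * sqrt(pi)` um, about
#' 487.42 um), keeps fields containing at least `min_tumour_frac` segmented
#' tumour, and thresholds the aggregated density at `cutoff_per_mm2`.
#'
#' @param hpf_diameter_mm Manual HPF diameter in mm (default 0.55).
#' @param min_tumour_frac Minimum tumour fraction for field eligibility
#'   (default 0.10).
#' @param cutoff_per_mm2 TIL-High/Low cut-off in iTILs per mm^2 tumour
#'   (default 17).
#' @param manual_cutoff_per_hpf Manual cut-off in TILs per HPF (default 2).
#' @param manual_hpf_count Number of HPFs in the manual protocol (default 5).
#' @return A `scoring_config` list; `field_side_um` and `field_area_mm2`
#'   are derived (field area equals the circular HPF area).
#' @export
scoring_config <- function(hpf_diameter_mm = 0.55, min_tumour_frac = 0.10,
                           cutoff_per_mm2 = 17.0, manual_cutoff_per_hpf = 2.0,
                           manual_hpf_count = 5L) {
  stopifnot_scalar_number(hpf_diameter_mm, "hpf_diameter_mm", positive = TRUE)
  side_um <- 1000 * (hpf_diameter_mm / 2) * sqrt(pi)
  list(hpf_diameter_mm = hpf_diameter_mm,
       field_side_um = side_um,
       field_area_mm2 = pi * (hpf_diameter_mm / 2)^2,
       min_tumour_frac = min_tumour_frac,
       cutoff_per_mm2 = cutoff_per_mm2,
       manual_cutoff_per_hpf = manual_cutoff_per_hpf,
       manual_hpf_count = as.integer(manual_hpf_count))
}

#' Assign detected TILs to tissue compartments
#'
#' Labels each point with the tumour/stroma/necrosis class at its
#' coordinate in the predicted TSN mask (nearest-neighbour pixel lookup in
#' the shared micron frame). Tumour-labelled points are the iTILs; necrosis
#' points are recorded but never scored; points outside the mask extent are
#' labelled `"unassigned"`.
#'
#' @param points A [point_set()].
#' @param tsn_mask A [label_raster()] with tumour/stroma/necrosis classes.
#' @return The [point_set()] with `compartment` filled in.
#' @export
assign_compartment <- function(points, tsn_mask) {
  if (nrow(points) == 0) return(points)
  cls <- raster_class_at(tsn_mask, points$x_um, points$y_um)
  cls[is.na(cls) | cls == "other"] <- "unassigned"
  points$compartment <- cls
  points
}

#' Lay an HPF-equivalent field grid over the tumour mask
#'
#' Non-overlapping axis-aligned squares with side `field_side_um` snapped
#' to a whole number of pixels at the mask resolution (975 px at 0.5 MPP;
#' area error < 0.2%), anchored at the top-left corner of the tumour
#' bounding box and covering it (edge fields may extend past the box).
#'
#' @param tumour_mask A [label_raster()] containing a `"tumour"` class.
#' @param config A [scoring_config()].
#' @return Data frame of half-open field bounds in microns
#'   (`index, x0, y0, x1, y1`), empty when the mask holds no tumour.
#' @export
build_field_grid <- function(tumour_mask, config = scoring_config()) {
  id <- raster_class_id(tumour_mask, "tumour")
  hit <- which(tumour_mask$grid == id, arr.ind = TRUE)
  empty <- data.frame(index = integer(), x0 = numeric(), y0 = numeric(),
                      x1 = numeric(), y1 = numeric())
  if (nrow(hit) == 0) return(empty)
  side_px <- max(1L, as.integer(round(config$field_side_um / tumour_mask$mpp)))
  side_um <- side_px * tumour_mask$mpp
  bx <- range(hit[, 2]) - 1L    # 0-based pixel bbox
  by <- range(hit[, 1]) - 1L
  nx <- ceiling((bx[2] - bx[1] + 1L) / side_px)
  ny <- ceiling((by[2] - by[1] + 1L) / side_px)
  ox <- tumour_mask$origin_um[1] + bx[1] * tumour_mask$mpp
  oy <- tumour_mask$origin_um[2] + by[1] * tumour_mask$mpp
  g <- expand.grid(i = seq_len(nx) - 1L, j = seq_len(ny) - 1L)
  data.frame(index = seq_len(nrow(g)),
             x0 = ox + g$i * side_um, y0 = oy + g$j * side_um,
             x1 = ox + (g$i + 1) * side_um, y1 = oy + (g$j + 1) * side_um)
}

#' Score one field
#'
#' Counts tumour-compartment points inside the half-open field square
#' (`L_i`), measures the tumour pixel area inside the field in mm^2
#' (`T_i`), and derives the field density `L_i / T_i`. A field is eligible
#' when its tumour content is at least `min_tumour_frac` of the full field
#' area.
#'
#' @param field One row of [build_field_grid()] output (or any list with
#'   micron bounds `x0, y0, x1, y1`).
#' @param tumour_mask A [label_raster()] with a `"tumour"` class.
#' @param itil_points A [point_set()] with compartments assigned.
#' @param config A [scoring_config()].
#' @return One-row data frame: `index, x0, y0, x1, y1, T_mm2, L, density,
#'   eligible` (`density` is `NA` when `T_i` is 0).
#' @export
score_field <- function(field, tumour_mask, itil_points,
                        config = scoring_config()) {
  id <- raster_class_id(tumour_mask, "tumour")
  ext <- raster_extent_px(tumour_mask)
  px0 <- max(0L, as.integer(round((field$x0 - tumour_mask$origin_um[1]) / tumour_mask$mpp)))
  py0 <- max(0L, as.integer(round((field$y0 - tumour_mask$origin_um[2]) / tumour_mask$mpp)))
  px1 <- min(ext[1], as.integer(round((field$x1 - tumour_mask$origin_um[1]) / tumour_mask$mpp)))
  py1 <- min(ext[2], as.integer(round((field$y1 - tumour_mask$origin_um[2]) / tumour_mask$mpp)))
  t_px <- if (px1 > px0 && py1 > py0) {
    sum(tumour_mask$grid[(py0 + 1):py1, (px0 + 1):px1] == id)
  } else 0L
  t_mm2 <- t_px * (tumour_mask$mpp / 1000)^2
  l <- if (nrow(itil_points) == 0) 0L else {
    sum(!is.na(itil_points$compartment) & itil_points$compartment == "tumour" &
          itil_points$x_um >= field$x0 & itil_points$x_um < field$x1 &
          itil_points$y_um >= field$y0 & itil_points$y_um < field$y1)
  }
  field_area <- (field$x1 - field$x0) * (field$y1 - field$y0) / 1e6
  data.frame(index = if (is.null(field$index)) NA_integer_ else field$index,
             x0 = field$x0, y0 = field$y0, x1 = field$x1, y1 = field$y1,
             T_mm2 = t_mm2, L = as.integer(l),
             density = if (t_mm2 > 0) l / t_mm2 else NA_real_,
             eligible = t_mm2 / field_area >= config$min_tumour_frac)
}

#' Score every field of a grid
#'
#' @param fields Output of [build_field_grid()].
#' @inheritParams score_field
#' @return Data frame with one [score_field()] row per field.
#' @export
score_fields <- function(fields, tumour_mask, itil_points,
                         config = scoring_config()) {
  if (nrow(fields) == 0) {
    return(score_field(list(x0 = 0, y0 = 0, x1 = 0, y1 = 0, index = 1L),
                       tumour_mask, itil_points, config)[0, ])
  }
  do.call(rbind, lapply(seq_len(nrow(fields)), function(i) {
    score_field(fields[i, ], tumour_mask, itil_points, config)
  }))
}

#' Aggregate slide scores into the patient-level AI iTIL score
#'
#' Pools the eligible-field densities of all the patient's slides and takes
#' the median (even counts average the two central order statistics). The
#' TIL class is `"TIL-High"` when the score reaches the cut-off. With zero
#' eligible fields the score is undefined and the patient is flagged with
#' no class emitted.
#'
#' @param slides A list of slide scores (from [score_slide()]), or any list
#'   of objects carrying a `fields` data frame as produced by
#'   [score_fields()].
#' @param config A [scoring_config()].
#' @return A `patient_score`: list with `ai_itil_score`, `til_class`,
#'   `n_eligible_fields`, `densities` and `undefined` flag.
#' @export
ai_itil_score <- function(slides, config = scoring_config()) {
  if (inherits(slides, "slide_score")) slides <- list(slides)
  dens <- unlist(lapply(slides, function(s) {
    f <- s$fields
    f$density[f$eligible & !is.na(f$density)]
  }))
  if (length(dens) == 0) {
    return(structure(list(ai_itil_score = NA_real_, til_class = NA_character_,
                          n_eligible_fields = 0L, densities = numeric(),
                          undefined = TRUE),
                     class = "patient_score"))
  }
  score <- stats::median(dens)
  structure(list(ai_itil_score = score,
                 til_class = classify(score, config$cutoff_per_mm2),
                 n_eligible_fields = length(dens), densities = dens,
                 undefined = FALSE),
            class = "patient_score")
}

#' @export
print.patient_score <- function(x, ...) {
  if (x$undefined) {
    cat("<patient_score> undefined (no eligible fields)\n")
  } else {
    cat(sprintf("<patient_score> AI iTIL score %.2f per mm^2 tumour (%s, F = %d)\n",
                x$ai_itil_score, x$til_class, x$n_eligible_fields))
  }
  invisible(x)
}

#' Binary TIL classification at a density cut-off
#'
#' Scores at or above the cut-off are `"TIL-High"` (the good-prognosis
#' group), below it `"TIL-Low"`. The boundary convention (17.0 exactly is
#' High) is a documented choice; pass a different `cutoff` to move it.
#'
#' @param score AI iTIL score(s) in iTILs per mm^2 tumour.
#' @param cutoff Cut-off (default 17).
#' @return Character vector of `"TIL-High"` / `"TIL-Low"`.
#' @export
classify <- function(score, cutoff = 17) {
  if (any(!is.finite(score))) {
    itil_error("itil_invalid_argument", "score must be finite")
  }
  ifelse(score >= cutoff, "TIL-High", "TIL-Low")
}

#' Convert a per-HPF TIL count to a per-mm^2-tumour density
#'
#' The manual criterion counts TILs per circular high-power field; dividing
#' by the tumour area within the field (`tumour_fraction` times the HPF
#' area) expresses it on the automated score's scale. At 2 TILs/HPF and
#' diameter 0.55 mm this gives about 17 per mm^2 at 50% tumour and spans
#' 14-21 across 60-40% tumour.
#'
#' @param tils_per_hpf TIL count per HPF.
#' @param tumour_fraction Fraction of the HPF area occupied by tumour, in
#'   (0, 1].
#' @param hpf_diameter_mm HPF diameter in mm (default 0.55).
#' @return Density in TILs per mm^2 tumour.
#' @examples
#' round(hpf_equivalent_density(2, 0.5)) # 17
#' @export
hpf_equivalent_density <- function(tils_per_hpf, tumour_fraction,
                                   hpf_diameter_mm = 0.55) {
  stopifnot_scalar_number(hpf_diameter_mm, "hpf_diameter_mm", positive = TRUE)
  if (any(tumour_fraction <= 0 | tumour_fraction > 1)) {
    itil_error("itil_invalid_argument", "tumour_fraction must lie in (0, 1]")
  }
  tils_per_hpf / (tumour_fraction * pi * (hpf_diameter_mm / 2)^2)
}

#' Manual five-HPF TIL classification
#'
#' The manual protocol averages TIL counts over five HPFs and calls
#' patients TIL-High at a mean of 2 or more.
#'
#' @param per_hpf_counts Numeric TIL counts, one per HPF.
#' @param config A [scoring_config()] (supplies the cut-off and expected
#'   HPF count).
#' @return `"TIL-High"` or `"TIL-Low"`.
#' @export
manual_score_classify <- function(per_hpf_counts, config = scoring_config()) {
  if (length(per_hpf_counts) == 0) {
    itil_error("itil_invalid_argument", "per_hpf_counts must be nonempty")
  }
  if (length(per_hpf_counts) != config$manual_hpf_count) {
    itil_error("itil_invalid_argument",
               sprintf("expected %d HPF counts, got %d",
                       config$manual_hpf_count, length(per_hpf_counts)))
  }
  if (mean(per_hpf_counts) >= config$manual_cutoff_per_hpf) "TIL-High" else "TIL-Low"
}

#' Default slide-flagging criteria
#'
#' Rule-based thresholds marking slides whose automated analysis may be
#' unreliable (for example when too little tumour tissue is available).
#' Flagged slides still receive scores; the flag recommends manual review.
#'
#' @param min_tumour_area_mm2 Minimum total tumour area (default 1).
#' @param min_eligible_fields Minimum eligible field count (default 5,
#'   mirroring the five-HPF manual practice).
#' @param min_cancer_fraction Minimum cancerous fraction of detected tissue
#'   (default 0.05).
#' @param max_stain_failures Maximum tolerated stain-normalisation failures
#'   (default 0).
#' @return A `flag_criteria` list.
#' @export
flag_criteria <- function(min_tumour_area_mm2 = 1.0, min_eligible_fields = 5L,
                          min_cancer_fraction = 0.05, max_stain_failures = 0L) {
  list(min_tumour_area_mm2 = min_tumour_area_mm2,
       min_eligible_fields = as.integer(min_eligible_fields),
       min_cancer_fraction = min_cancer_fraction,
       max_stain_failures = as.integer(max_stain_failures))
}

#' Evaluate flagging criteria for one slide
#'
#' @param metrics Named list with any of `tumour_area_mm2`,
#'   `eligible_field_count`, `cancer_fraction_of_tissue`, `stain_failures`;
#'   absent metrics are not evaluated.
#' @param criteria A [flag_criteria()] list.
#' @return A `flag_report`: list with `flagged` and a data frame
#'   `criteria_triggered` (criterion, measured value, threshold).
#' @export
flag_slide <- function(metrics, criteria = flag_criteria()) {
  rows <- list()
  add <- function(name, value, threshold) {
    rows[[length(rows) + 1]] <<- data.frame(criterion = name, value = value,
                                            threshold = threshold)
  }
  if (!is.null(metrics$tumour_area_mm2) &&
      metrics$tumour_area_mm2 < criteria$min_tumour_area_mm2) {
    add("insufficient-tumour", metrics$tumour_area_mm2, criteria$min_tumour_area_mm2)
  }
  if (!is.null(metrics$eligible_field_count) &&
      metrics$eligible_field_count < criteria$min_eligible_fields) {
    add("too-few-fields", metrics$eligible_field_count, criteria$min_eligible_fields)
  }
  if (!is.null(metrics$cancer_fraction_of_tissue) &&
      metrics$cancer_fraction_of_tissue < criteria$min_cancer_fraction) {
    add("low-cancer-fraction", metrics$cancer_fraction_of_tissue,
        criteria$min_cancer_fraction)
  }
  if (!is.null(metrics$stain_failures) &&
      metrics$stain_failures > criteria$max_stain_failures) {
    add("stain-failure", metrics$stain_failures, criteria$max_stain_failures)
  }
  triggered <- if (length(rows)) do.call(rbind, rows) else
    data.frame(criterion = character(), value = numeric(), threshold = numeric())
  structure(list(flagged = nrow(triggered) > 0, criteria_triggered = triggered),
            class = "flag_report")
}

#' Summarise a cohort of patient scores
#'
#' Counts flagged and retained patients (flag rate as a percentage to one
#' decimal), tabulates TIL classes among retained patients and summarises
#' the score distribution.
#'
#' @param patients Data frame with a logical `flagged` column and optional
#'   `til_class` and `ai_itil_score` columns.
#' @return List with `n_total`, `n_flagged`, `n_retained`,
#'   `flag_rate_pct`, `til_class_counts`, `score_quantiles`.
#' @export
summarize_cohort <- function(patients) {
  if (nrow(patients) < 1) itil_error("itil_invalid_argument", "empty cohort")
  if (is.null(patients$flagged)) {
    itil_error("itil_invalid_argument", "`patients` needs a logical `flagged` column")
  }
  n <- nrow(patients)
  nf <- sum(patients$flagged)
  retained <- patients[!patients$flagged, , drop = FALSE]
  cls <- if (!is.null(retained$til_class)) {
    table(factor(retained$til_class, levels = c("TIL-High", "TIL-Low")))
  } else NULL
  qs <- if (!is.null(retained$ai_itil_score)) {
    stats::quantile(retained$ai_itil_score, c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE)
  } else NULL
  list(n_total = n, n_flagged = nf, n_retained = n - nf,
       flag_rate_pct = round(100 * nf / n, 1),
       til_class_counts = cls, score_quantiles = qs)
}
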