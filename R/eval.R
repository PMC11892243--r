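#' Detection evaluation configuration
#'
#' @param match_radius_um Maximum prediction-to-annotation Euclidean
#'   distance for a true positive (default 4, half the ~8 um average TIL
#'   diameter).
#' @param matching_policy `"greedy"` (confidence-descending, nearest first;
#'   the default) or `"optimal"` (maximum-cardinality one-to-one
#'   assignment, for sensitivity checks).
#' @return An `eval_config` list.
#' @export
eval_config <- function(match_radius_um = 4.0,
                        matching_policy = c("greedy", "optimal")) {
  stopifnot_scalar_number(match_radius_um, "match_radius_um", positive = TRUE)
  list(match_radius_um = match_radius_um,
       matching_policy = match.arg(matching_policy))
}

# maximum-cardinality bipartite matching by augmenting paths over the
# within-radius edge set; small instances only
max_bipartite_match <- function(adj, n_gt) {
  match_gt <- rep(NA_integer_, n_gt)
  match_pred <- rep(NA_integer_, length(adj))
  augment <- function(p, env) {
    for (g in adj[[p]]) {
      if (!env$visited[g]) {
        env$visited[g] <- TRUE
        if (is.na(match_gt[g]) || augment(match_gt[g], env)) {
          match_gt[g] <<- p
          match_pred[p] <<- g
          return(TRUE)
        }
      }
    }
    FALSE
  }
  for (p in seq_along(adj)) {
    env <- new.env(parent = emptyenv())
    env$visited <- rep(FALSE, n_gt)
    augment(p, env)
  }
  match_pred
}

#' Match predicted points to ground truth
#'
#' One-to-one matching under the radius rule: a prediction is a true
#' positive if matched to an annotation within `match_radius_um`. The
#' greedy policy processes predictions in descending confidence (ties by
#' (y, x)), each taking its nearest still-unmatched annotation within the
#' radius; the optimal policy maximises the number of matches.
#'
#' @param pred,gt [point_set()]s in the same micron frame.
#' @param config An [eval_config()].
#' @return A `match_result`: list with `pairs` (pred/gt indices and
#'   distance), `tp`, `fp`, `fn`, `precision`, `recall`, `f1`. Conventions:
#'   empty predictions against nonempty truth give precision 0; two empty
#'   sets give all metrics 1.
#' @export
match_points <- function(pred, gt, config = eval_config()) {
  np <- nrow(pred); ng <- nrow(gt)
  finish <- function(pairs) {
    tp <- nrow(pairs); fp <- np - tp; fn <- ng - tp
    precision <- if (np == 0) (if (ng == 0) 1 else 0) else tp / np
    recall <- if (ng == 0) (if (np == 0) 1 else 0) else tp / ng
    f1 <- if (precision + recall == 0) {
      if (np == 0 && ng == 0) 1 else 0
    } else 2 * precision * recall / (precision + recall)
    structure(list(pairs = pairs, tp = tp, fp = fp, fn = fn,
                   precision = precision, recall = recall, f1 = f1),
              class = "match_result")
  }
  empty_pairs <- data.frame(pred = integer(), gt = integer(), dist_um = numeric())
  if (np == 0 || ng == 0) return(finish(empty_pairs))

  r2 <- config$match_radius_um^2
  if (config$matching_policy == "greedy") {
    ord <- order(-pred$confidence, pred$y_um, pred$x_um)
    taken <- rep(FALSE, ng)
    rows <- list()
    for (p in ord) {
      d2 <- (gt$x_um - pred$x_um[p])^2 + (gt$y_um - pred$y_um[p])^2
      d2[taken] <- Inf
      g <- which.min(d2)
      if (length(g) == 1 && d2[g] <= r2) {
        taken[g] <- TRUE
        rows[[length(rows) + 1]] <- data.frame(pred = p, gt = g,
                                               dist_um = sqrt(d2[g]))
      }
    }
    pairs <- if (length(rows)) do.call(rbind, rows) else empty_pairs
  } else {
    adj <- lapply(seq_len(np), function(p) {
      d2 <- (gt$x_um - pred$x_um[p])^2 + (gt$y_um - pred$y_um[p])^2
      which(d2 <= r2)
    })
    mp <- max_bipartite_match(adj, ng)
    hit <- which(!is.na(mp))
    pairs <- if (length(hit)) data.frame(
      pred = hit, gt = mp[hit],
      dist_um = sqrt((gt$x_um[mp[hit]] - pred$x_um[hit])^2 +
                       (gt$y_um[mp[hit]] - pred$y_um[hit])^2)
    ) else empty_pairs
  }
  finish(pairs)
}

#' Average precision of a confidence-ranked detector
#'
#' Traces the precision-recall curve by descending confidence and
#' integrates it with the all-points rule (sum over true positives of
#' precision times the recall increment, no 11-point interpolation).
#' Because the greedy matcher processes predictions in confidence order,
#' thresholding at any confidence keeps a prefix of the ranking, so the
#' per-threshold matchings coincide with the single ranked pass.
#'
#' @param pred A [point_set()] with confidences.
#' @param gt Ground-truth [point_set()].
#' @param config An [eval_config()].
#' @return AP in [0, 1].
#' @export
average_precision <- function(pred, gt, config = eval_config()) {
  if (nrow(gt) == 0) return(if (nrow(pred) == 0) 1 else 0)
  if (nrow(pred) == 0) return(0)
  ord <- order(-pred$confidence, pred$y_um, pred$x_um)
  r2 <- config$match_radius_um^2
  taken <- rep(FALSE, nrow(gt))
  tp_flag <- logical(length(ord))
  for (k in seq_along(ord)) {
    p <- ord[k]
    d2 <- (gt$x_um - pred$x_um[p])^2 + (gt$y_um - pred$y_um[p])^2
    d2[taken] <- Inf
    g <- which.min(d2)
    if (length(g) == 1 && d2[g] <= r2) {
      taken[g] <- TRUE
      tp_flag[k] <- TRUE
    }
  }
  cum_tp <- cumsum(tp_flag)
  precision <- cum_tp / seq_along(ord)
  recall <- cum_tp / nrow(gt)
  sum(precision[tp_flag] * diff(c(0, recall))[tp_flag])
}

#' Pixel-level segmentation F1 (Dice) for one class
#'
#' `2 |A intersect B| / (|A| + |B|)` over the pixels of class `cls`. Two
#' masks with no pixels of the class agree perfectly (1).
#'
#' @param pred_mask,gt_mask [label_raster()]s with identical extent and
#'   resolution.
#' @param cls Class name to evaluate.
#' @return Dice/F1 in [0, 1].
#' @export
segmentation_f1 <- function(pred_mask, gt_mask, cls) {
  if (!identical(dim(pred_mask$grid), dim(gt_mask$grid)) ||
      pred_mask$mpp != gt_mask$mpp) {
    itil_error("itil_invalid_argument", "masks must share extent and resolution")
  }
  a <- pred_mask$grid == raster_class_id(pred_mask, cls)
  b <- gt_mask$grid == raster_class_id(gt_mask, cls)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Precision/recall/F1 across confidence thresholds
#'
#' Filters predictions below each threshold, re-evaluates the matching and
#' reports per-threshold metrics plus the F1-maximising threshold (ties go
#' to the lowest threshold). This is the sweep used to select the 0.35
#' confidence gate.
#'
#' @param pred,gt [point_set()]s.
#' @param thresholds Numeric thresholds in [0, 1].
#' @param config An [eval_config()].
#' @return List with `table` (threshold, n_pred, tp, precision, recall,
#'   f1) and `best_threshold`.
#' @export
confidence_sweep <- function(pred, gt, thresholds = seq(0, 0.95, by = 0.05),
                             config = eval_config()) {
  if (any(thresholds < 0 | thresholds > 1)) {
    itil_error("itil_invalid_argument", "thresholds must lie in [0, 1]")
  }
  thresholds <- sort(thresholds)
  rows <- lapply(thresholds, function(t) {
    keep <- pred[pred$confidence >= t, , drop = FALSE]
    class(keep) <- c("point_set", "data.frame")
    m <- match_points(keep, gt, config)
    data.frame(threshold = t, n_pred = nrow(keep), tp = m$tp,
               precision = m$precision, recall = m$recall, f1 = m$f1)
  })
  tab <- do.call(rbind, rows)
  best <- tab$threshold[which.max(tab$f1)]   # which.max takes the first (lowest)
  list(table = tab, best_threshold = best)
}
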