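# Segmentation metric suite: pixel confusion (IoU, Dice), instance matching
# (precision, recall, small-object recall) and COCO-protocol mAP.

#' Pixel confusion between prediction and ground truth
#'
#' Computed class-agnostically on the union-of-instances foreground of each
#' side: TP/FP/FN are pixel counts of the overlap, prediction-only, and
#' truth-only regions.
#'
#' @param pred,gt instance tables in the same pixel frame.
#' @param width,height frame size in pixels.
#' @return one-row tibble with `TP`, `FP`, `FN`.
#' @export
pixel_confusion <- function(pred, gt, width, height) {
  pm <- union_mask(pred, width, height)
  gm <- union_mask(gt, width, height)
  tibble::tibble(TP = sum(pm & gm), FP = sum(pm & !gm), FN = sum(!pm & gm))
}

#' Pixel IoU from a confusion
#'
#' `IoU = TP / (TP + FP + FN)`.
#'
#' @param conf confusion tibble from [pixel_confusion()].
#' @return IoU in `[0, 1]`.
#' @export
iou_score <- function(conf) {
  denom <- conf$TP + conf$FP + conf$FN
  if (denom == 0) {
    abort("IoU undefined: both masks empty", class = "shellcarbon_metric_error")
  }
  conf$TP / denom
}

#' Dice coefficient from a confusion
#'
#' `Dice = 2 TP / (2 TP + FP + FN)`, equivalently `2 IoU / (1 + IoU)`.
#'
#' @inheritParams iou_score
#' @return Dice in `[0, 1]`.
#' @export
dice_score <- function(conf) {
  denom <- 2 * conf$TP + conf$FP + conf$FN
  if (denom == 0) {
    abort("Dice undefined: both masks empty", class = "shellcarbon_metric_error")
  }
  2 * conf$TP / denom
}

#' Match predicted instances to ground truth
#'
#' COCO-style greedy matching: predictions are visited in order of
#' descending score and each takes the highest-IoU still-unmatched ground
#' truth of the same class, provided the IoU reaches the threshold.
#' Matching is one-to-one.
#'
#' @param pred,gt instance tables (predictions should carry scores; missing
#'   scores are treated as 1).
#' @param iou_threshold minimum mask IoU for a match.
#' @return list with `matches` (tibble `pred_id`, `gt_id`, `iou`),
#'   `unmatched_pred`, `unmatched_gt` (instance id vectors) and `threshold`.
#' @export
match_instances <- function(pred, gt, iou_threshold = 0.5) {
  score <- ifelse(is.na(pred$score), 1, pred$score)
  ord <- order(-score)
  gt_taken <- rep(FALSE, nrow(gt))
  matches <- list()
  for (i in ord) {
    p <- pred[i, ]
    best_j <- 0L; best_iou <- 0
    for (j in seq_len(nrow(gt))) {
      if (gt_taken[j] || gt$class[j] != p$class) next
      g <- gt[j, ]
      if (p$x >= g$x + g$w || g$x >= p$x + p$w ||
          p$y >= g$y + g$h || g$y >= p$y + p$h) next
      v <- mask_iou(p, g)
      if (v > best_iou) { best_iou <- v; best_j <- j }
    }
    if (best_j > 0L && best_iou >= iou_threshold) {
      gt_taken[best_j] <- TRUE
      matches[[length(matches) + 1L]] <- tibble::tibble(
        pred_id = p$instance_id, gt_id = gt$instance_id[best_j],
        iou = best_iou)
    }
  }
  m <- if (length(matches)) dplyr::bind_rows(matches) else
    tibble::tibble(pred_id = integer(), gt_id = integer(), iou = double())
  list(matches = m,
       unmatched_pred = setdiff(pred$instance_id, m$pred_id),
       unmatched_gt = setdiff(gt$instance_id, m$gt_id),
       threshold = iou_threshold)
}

#' Instance-level precision and recall
#'
#' @param match result of [match_instances()].
#' @return one-row tibble with `precision` and `recall`.
#' @export
detection_pr <- function(match) {
  n_match <- nrow(match$matches)
  n_pred <- n_match + length(match$unmatched_pred)
  n_gt <- n_match + length(match$unmatched_gt)
  if (n_pred == 0 || n_gt == 0) {
    abort("precision/recall undefined: no predictions or no ground truth",
          class = "shellcarbon_metric_error")
  }
  tibble::tibble(precision = n_match / n_pred, recall = n_match / n_gt)
}

#' Recall restricted to small ground-truth objects
#'
#' @param match result of [match_instances()].
#' @param gt the ground-truth instance table used for the matching.
#' @param area_threshold_px2 mask area below which a truth counts as small
#'   (default 32^2 px, the COCO convention).
#' @return recall over small truths.
#' @export
small_object_recall <- function(match, gt, area_threshold_px2 = 1024) {
  small <- gt$instance_id[gt$area_px < area_threshold_px2]
  if (length(small) == 0) {
    abort("small-object recall undefined: no ground truth below the threshold",
          class = "shellcarbon_metric_error")
  }
  sum(match$matches$gt_id %in% small) / length(small)
}

#' Average precision for one class at one IoU threshold
#'
#' COCO-variant AP: predictions of the class are ranked by score, matched
#' greedily against the class's truths, the precision envelope (monotone
#' non-increasing) is taken over the PR points, and precision is averaged
#' at 101 equally spaced recall levels 0, 0.01, ..., 1.
#'
#' @param pred,gt instance tables.
#' @param class class label to evaluate.
#' @param iou_threshold mask IoU for a correct detection.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(pred, gt, class, iou_threshold = 0.5) {
  gt_c <- gt[gt$class == class, ]
  n_gt <- nrow(gt_c)
  if (n_gt == 0) {
    abort(sprintf("no ground truth of class '%s'", class),
          class = "shellcarbon_metric_error")
  }
  pred_c <- pred[pred$class == class, ]
  if (nrow(pred_c) == 0) return(0)
  score <- ifelse(is.na(pred_c$score), 1, pred_c$score)
  ord <- order(-score)
  gt_taken <- rep(FALSE, n_gt)
  tp <- logical(length(ord))
  for (k in seq_along(ord)) {
    p <- pred_c[ord[k], ]
    best_j <- 0L; best_iou <- 0
    for (j in seq_len(n_gt)) {
      if (gt_taken[j]) next
      v <- mask_iou(p, gt_c[j, ])
      if (v > best_iou) { best_iou <- v; best_j <- j }
    }
    if (best_j > 0L && best_iou >= iou_threshold) {
      gt_taken[best_j] <- TRUE
      tp[k] <- TRUE
    }
  }
  cum_tp <- cumsum(tp)
  precision <- cum_tp / seq_along(tp)
  recall <- cum_tp / n_gt
  # monotone precision envelope, then 101-point recall sampling
  env <- rev(cummax(rev(precision)))
  levels <- seq(0, 1, by = 0.01)
  p_at <- vapply(levels, function(r) {
    ok <- recall >= r
    if (any(ok)) max(env[ok]) else 0
  }, double(1))
  mean(p_at)
}

#' Mean average precision over the COCO IoU sweep
#'
#' AP is computed per class present in the ground truth and per IoU
#' threshold 0.50 to 0.95 in steps of 0.05, averaged over thresholds, then
#' arithmetically averaged over classes. Classes absent from the ground
#' truth are excluded (with a message).
#'
#' @param pred,gt instance tables.
#' @param iou_thresholds IoU sweep.
#' @return list with `mAP` and a per-class/threshold `ap` tibble.
#' @export
mean_average_precision <- function(pred, gt,
                                   iou_thresholds = seq(0.5, 0.95, by = 0.05)) {
  classes <- sort(unique(gt$class))
  skipped <- setdiff(unique(pred$class), classes)
  if (length(skipped)) {
    inform(sprintf("classes with no ground truth excluded from mAP: %s",
                   paste(skipped, collapse = ", ")))
  }
  if (length(classes) == 0) {
    abort("mAP undefined: empty ground truth", class = "shellcarbon_metric_error")
  }
  grid <- tidyr::expand_grid(class = classes, iou = iou_thresholds)
  grid$ap <- purrr::map2_dbl(grid$class, grid$iou, function(cl, th) {
    average_precision(pred, gt, cl, th)
  })
  per_class <- grid |> group_by(.data$class) |>
    summarise(ap = mean(.data$ap), .groups = "drop")
  list(mAP = mean(per_class$ap), ap = grid, per_class = per_class)
}

#' Agreement between model and manual dimension measurements
#'
#' Squared Pearson correlation of pooled model-vs-manual measurement pairs
#' (lengths and widths together). Note this is a correlation, not an
#' identity check: a constant multiplicative bias still yields 1.
#'
#' @param model,manual numeric vectors of paired measurements (mm).
#' @return R^2 in `[0, 1]`.
#' @export
dimension_agreement <- function(model, manual) {
  stopifnot(length(model) == length(manual))
  if (length(model) < 2) {
    abort("need at least 2 pairs", class = "shellcarbon_data_error")
  }
  if (var(model) == 0 || var(manual) == 0) {
    abort("agreement undefined: zero variance", class = "shellcarbon_data_error")
  }
  cor(model, manual)^2
}

#' Full evaluation report
#'
#' Bundles the metric suite for one panel: COCO mAP, dataset-pooled pixel
#' IoU and Dice, instance precision/recall at the matching threshold, and
#' small-object recall. Metrics that are undefined on the given input
#' (e.g. small-object recall when no truth is small) are reported as `NA`.
#'
#' @param pred,gt [shell_annotations()] objects on the same frame.
#' @param config a [run_config()].
#' @return one-row tibble.
#' @export
evaluate_predictions <- function(pred, gt, config = run_config()) {
  if (pred$width != gt$width || pred$height != gt$height) {
    abort("prediction and ground-truth frames differ",
          class = "shellcarbon_registration_error")
  }
  conf <- pixel_confusion(pred$instances, gt$instances, gt$width, gt$height)
  match <- match_instances(pred$instances, gt$instances, config$match_iou)
  pr <- detection_pr(match)
  sor <- tryCatch(
    small_object_recall(match, gt$instances, config$small_area_px2),
    shellcarbon_metric_error = function(e) NA_real_)
  map <- mean_average_precision(pred$instances, gt$instances)
  tibble::tibble(
    mAP = map$mAP,
    pixel_iou = iou_score(conf),
    dice = dice_score(conf),
    precision = pr$precision,
    recall = pr$recall,
    small_object_recall = sor
  )
}
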