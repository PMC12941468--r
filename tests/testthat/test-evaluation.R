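test_that("pixel confusion counts hand-enumerable toy masks", {
  # pred: 3x3 square (9 px); gt: 3x4 rectangle (12 px); overlap 2x3 = 6 px
  pred <- square_instance(2, 2, 3, width = 10, height = 10)
  gm <- matrix(FALSE, 10, 10); gm[4:6, 3:6] <- TRUE
  gt <- instance_from_mask(gm, "barnacle")
  conf <- pixel_confusion(pred, gt, 10, 10)
  expect_equal(conf$TP, 6)
  expect_equal(conf$FP, 3)
  expect_equal(conf$FN, 6)
  expect_equal(iou_score(conf), 0.4)
  expect_equal(dice_score(conf), 4 / 7)

  # identical sets
  conf2 <- pixel_confusion(pred, pred, 10, 10)
  expect_equal(conf2$FP + conf2$FN, 0)
  expect_equal(iou_score(conf2), 1)

  # disjoint masks of area 10 and 20
  a <- instance_from_mask({m <- matrix(FALSE, 20, 20); m[1:2, 1:5] <- TRUE; m},
                          "barnacle")
  b <- instance_from_mask({m <- matrix(FALSE, 20, 20); m[10:13, 10:14] <- TRUE; m},
                          "barnacle")
  conf3 <- pixel_confusion(a, b, 20, 20)
  expect_equal(unlist(conf3[c("TP", "FP", "FN")]),
               c(TP = 0, FP = 10, FN = 20))
  expect_error(iou_score(tibble::tibble(TP = 0, FP = 0, FN = 0)),
               class = "shellcarbon_metric_error")
})

test_that("the Dice-IoU identity holds on random mask pairs", {
  set.seed(123)
  for (k in 1:1000) {
    m1 <- matrix(stats::runif(64) < 0.4, 8, 8)
    m2 <- matrix(stats::runif(64) < 0.4, 8, 8)
    if (!any(m1)) m1[1, 1] <- TRUE
    if (!any(m2)) m2[2, 2] <- TRUE
    conf <- pixel_confusion(instance_from_mask(m1, "x"),
                            instance_from_mask(m2, "x"), 8, 8)
    iou <- iou_score(conf)
    expect_equal(dice_score(conf), 2 * iou / (1 + iou))
  }
})

test_that("greedy matching is one-to-one and score-ordered", {
  gt <- square_instance(10, 10, 20, id = 1L)
  preds <- dplyr::bind_rows(
    square_instance(10, 10, 20, score = 0.9, id = 1L),
    square_instance(11, 10, 20, score = 0.8, id = 2L))
  m <- match_instances(preds, gt, 0.5)
  expect_equal(nrow(m$matches), 1L)
  expect_equal(m$matches$pred_id, 1L)     # higher score takes the truth
  expect_equal(m$unmatched_pred, 2L)

  # perfect predictions match everything
  gt2 <- dplyr::bind_rows(
    square_instance(5, 5, 10, id = 1L),
    square_instance(40, 40, 12, "bivalve", id = 2L))
  preds2 <- dplyr::mutate(gt2, score = 1)
  m2 <- match_instances(preds2, gt2, 0.5)
  expect_equal(nrow(m2$matches), 2L)
  expect_length(m2$unmatched_gt, 0L)
  expect_true(all(m2$matches$iou == 1))

  # class labels must agree
  cross <- dplyr::mutate(gt, class = "bivalve", score = 1)
  m3 <- match_instances(cross, gt, 0.5)
  expect_equal(nrow(m3$matches), 0L)
})

test_that("greedy matching attains the exhaustive-assignment optimum on a toy set", {
  # 3 preds / 3 gts with a constructed IoU structure
  gts <- dplyr::bind_rows(
    square_instance(0, 0, 10, id = 1L),
    square_instance(30, 0, 10, id = 2L),
    square_instance(60, 0, 10, id = 3L))
  preds <- dplyr::bind_rows(
    square_instance(1, 0, 10, score = 0.95, id = 1L),   # best for gt 1
    square_instance(32, 0, 10, score = 0.90, id = 2L),  # best for gt 2
    square_instance(61, 1, 10, score = 0.85, id = 3L))  # best for gt 3
  m <- match_instances(preds, gts, 0.3)
  expect_equal(nrow(m$matches), 3L)
  # brute force over all assignments maximizing total IoU above threshold
  iou_mat <- outer(1:3, 1:3, Vectorize(function(i, j)
    mask_iou(preds[i, ], gts[j, ])))
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  best <- max(vapply(perms, function(p) {
    v <- iou_mat[cbind(1:3, p)]
    sum(v[v >= 0.3])
  }, double(1)))
  expect_equal(sum(m$matches$iou), best, tolerance = 1e-12)
})

test_that("average precision equals the hand-computed interpolated value", {
  # 4 gts; 4 preds with scores .9 .8 .7 .6 and correctness T F T T
  gts <- dplyr::bind_rows(lapply(1:4, function(i)
    square_instance(30 * (i - 1), 0, 10, id = i, width = 200, height = 40)))
  ok <- function(i, id, s) square_instance(30 * (i - 1), 0, 10, score = s,
                                           id = id, width = 200, height = 40)
  miss <- function(id, s) square_instance(150, 20, 10, score = s, id = id,
                                          width = 200, height = 40)
  preds <- dplyr::bind_rows(ok(1, 1L, 0.9), miss(2L, 0.8),
                            ok(2, 3L, 0.7), ok(3, 4L, 0.6))
  ap <- average_precision(preds, gts, class = "barnacle",
                          iou_threshold = 0.5)
  # PR points: (.25,1) (.25,.5) (.5,2/3) (.75,.75); envelope 1,.75,.75,.75
  # 101-point sampling: 26 levels at 1, 50 at .75, 25 at 0
  expect_equal(ap, (26 * 1 + 50 * 0.75) / 101)

  # no correct predictions -> AP 0
  bad <- dplyr::bind_rows(miss(1L, 0.9), miss(2L, 0.8))
  expect_equal(average_precision(bad, gts, "barnacle", 0.5), 0)
})

test_that("perfect predictions give mAP 1 and no-overlap predictions give 0", {
  sc <- clean_scene()
  gt <- sc$annotations$instances
  perfect <- dplyr::mutate(gt, score = 1)
  res <- mean_average_precision(perfect, gt)
  expect_equal(res$mAP, 1)
  expect_true(all(res$ap$ap == 1))

  shifted <- translate_instances(gt[gt$x < 300, ], 400, 0)
  shifted$score <- 1
  expect_equal(mean_average_precision(shifted, gt)$mAP, 0)
})

test_that("mAP is invariant to positive score rescaling and monotone in IoU", {
  sc <- clean_scene()
  gt <- sc$annotations$instances
  pred <- segment_panel(sc$panel, run_config())
  m1 <- mean_average_precision(pred, gt)
  pred2 <- dplyr::mutate(pred, score = score * 0.37)
  m2 <- mean_average_precision(pred2, gt)
  expect_equal(m1$mAP, m2$mAP)
  # AP at stricter thresholds never exceeds AP at looser ones
  per_thr <- m1$ap |>
    dplyr::group_by(iou) |>
    dplyr::summarise(ap = mean(ap), .groups = "drop") |>
    dplyr::arrange(iou)
  expect_true(all(diff(per_thr$ap) <= 1e-12))
})

test_that("precision, recall and small-object recall follow instance counts", {
  # 8 matched, 1 extra pred (FP), 2 extra gts (FN)
  gts <- dplyr::bind_rows(lapply(1:10, function(i)
    square_instance(22 * (i - 1), 0, 12, id = i, width = 250, height = 60)))
  preds <- dplyr::bind_rows(
    lapply(1:8, function(i) square_instance(22 * (i - 1), 0, 12, score = 0.9,
                                            id = i, width = 250, height = 60)),
    square_instance(100, 40, 12, score = 0.5, id = 9L,
                    width = 250, height = 60))
  m <- match_instances(preds, gts, 0.5)
  pr <- detection_pr(m)
  expect_equal(pr$precision, 8 / 9)
  expect_equal(pr$recall, 0.8)

  # all gts here are 144 px < 1024: small-object recall = overall recall
  expect_equal(small_object_recall(m, gts, 1024), 0.8)
  # no gt below a 10 px^2 threshold -> undefined
  expect_error(small_object_recall(m, gts, 10),
               class = "shellcarbon_metric_error")
})

test_that("dimension agreement is a squared correlation, not an identity check", {
  x <- c(3.1, 4.8, 6.2, 9.5, 12.0)
  expect_equal(dimension_agreement(x, x), 1)
  expect_equal(dimension_agreement(2 * x, x), 1)   # bias-blind by design
  expect_error(dimension_agreement(rep(1, 5), x),
               class = "shellcarbon_data_error")

  # n = 83 pairs with sample correlation forced to sqrt(0.95)
  set.seed(77)
  pairs <- MASS::mvrnorm(83, mu = c(10, 10),
                         Sigma = matrix(c(1, sqrt(0.95), sqrt(0.95), 1), 2),
                         empirical = TRUE)
  expect_equal(dimension_agreement(pairs[, 1], pairs[, 2]), 0.95,
               tolerance = 1e-10)
})

test_that("the full report bundles all metrics and checks frames", {
  sc <- clean_scene()
  gt <- sc$annotations
  perfect <- shell_annotations(dplyr::mutate(gt$instances, score = 1),
                               gt$width, gt$height)
  rep <- evaluate_predictions(perfect, gt)
  expect_equal(rep$mAP, 1)
  expect_equal(rep$pixel_iou, 1)
  expect_equal(rep$dice, 1)
  expect_equal(rep$precision, 1)
  expect_equal(rep$recall, 1)

  other <- shell_annotations(empty_instances(), 10, 10)
  expect_error(evaluate_predictions(other, gt),
               class = "shellcarbon_registration_error")
})
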