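test_that("tiling covers the image with edge-anchored strides", {
  t1 <- tile_image(1024, 1024, window = 512, overlap = 0)
  expect_equal(nrow(t1), 4L)
  expect_setequal(unique(t1$x0), c(0, 512))

  t2 <- tile_image(1000, 1000, window = 512, overlap = 64)
  expect_setequal(unique(t2$x0), c(0, 448, 488))
  expect_setequal(unique(t2$y0), c(0, 448, 488))
  expect_equal(nrow(t2), 9L)

  t3 <- tile_image(300, 300, window = 512)
  expect_equal(nrow(t3), 1L)
  expect_equal(t3$w, 300)

  # coverage: every pixel of a 777x530 image lies in >= 1 tile
  t4 <- tile_image(777, 530, window = 256, overlap = 32)
  covered <- matrix(FALSE, 530, 777)
  for (i in seq_len(nrow(t4))) {
    covered[(t4$y0[i] + 1):(t4$y0[i] + t4$h[i]),
            (t4$x0[i] + 1):(t4$x0[i] + t4$w[i])] <- TRUE
  }
  expect_true(all(covered))
  expect_error(tile_image(100, 100, window = 32, overlap = 40),
               class = "shellcarbon_config_error")
})

test_that("the baseline finds nothing on a blank tile", {
  expect_equal(nrow(segment_baseline(matrix(0.4, 128, 128))), 0L)
})

test_that("the baseline segments and classifies well-separated shells", {
  sc <- clean_scene()
  inst <- segment_panel(sc$panel, run_config())
  expect_equal(nrow(inst), nrow(sc$truth))
  match <- match_instances(inst, sc$annotations$instances, 0.5)
  recall <- nrow(match$matches) /
    (nrow(match$matches) + length(match$unmatched_gt))
  expect_gte(recall, 0.95)
})

test_that("watershed splits two moderately overlapping shells", {
  spec <- scenario_spec(n_barnacle = 2, n_bivalve = 0, scale_px_per_cm = 20,
                        noise_sd = 0, illumination = 0, texture = 0,
                        max_overlap = 0.3, panel_width_cm = 8,
                        panel_height_cm = 8)
  # two 12 mm barnacles whose centers sit 7 mm apart: ~30% mask overlap
  mk <- function(id, cx) {
    em <- shellcarbon:::ellipse_mask(cx, 80, 12, 11, 0, 160, 160)
    tibble::tibble(instance_id = id, class = "barnacle", score = NA_real_,
                   x = em$x, y = em$y, w = em$w, h = em$h,
                   area_px = as.double(sum(em$mask)), mask = list(em$mask),
                   cx = cx, cy = 80, theta = 0, L_mm = 12, B_mm = 11)
  }
  pop <- dplyr::bind_rows(mk(1L, 70), mk(2L, 84))
  ov <- shellcarbon:::mask_containment(pop[1, ], pop[2, ])
  expect_gt(ov, 0.2)
  sc <- render_scene(pop, spec, seed = 1)
  inst <- segment_baseline(sc$panel$pixels, run_config())
  expect_equal(nrow(inst), 2L)
})

test_that("merging translates tiles and fuses split instances", {
  # an instance split across two overlapping tiles into two half-masks
  full <- ellipse_instance(60, 50, 30, 18, width = 120, height = 100)
  fm <- full_mask(full, 120, 100)
  left <- fm; left[, 76:120] <- FALSE
  right <- fm; right[, 1:35] <- FALSE
  a <- instance_from_mask(left, "bivalve", score = 0.8, instance_id = 1L)
  b <- instance_from_mask(right, "bivalve", score = 0.6, instance_id = 2L)
  expect_gt(mask_iou(a, b), 0.5)
  merged <- merge_tile_predictions(
    list(a, b), tibble::tibble(x0 = c(0, 0), y0 = c(0, 0)), merge_iou = 0.5)
  expect_equal(nrow(merged), 1L)
  expect_identical(full_mask(merged[1, ], 120, 100), fm)
  expect_equal(merged$score, 0.8)
})

test_that("containment fuses a fragment into the full mask even at low IoU", {
  full <- ellipse_instance(60, 50, 30, 18, width = 120, height = 100,
                           score = 0.9)
  fm <- full_mask(full, 120, 100)
  frag <- fm; frag[, 1:80] <- FALSE       # small sliver, IoU << 0.5
  b <- instance_from_mask(frag, "bivalve", score = 0.3, instance_id = 2L)
  expect_lt(mask_iou(full, b), 0.5)
  merged <- merge_instances(dplyr::bind_rows(full, b))
  expect_equal(nrow(merged), 1L)
})

test_that("merging is idempotent and preserves separated instances", {
  inst <- dplyr::bind_rows(
    square_instance(5, 5, 20, id = 1L, score = 0.9),
    square_instance(60, 60, 20, id = 2L, score = 0.8))
  m1 <- merge_instances(inst)
  expect_equal(nrow(m1), 2L)
  m2 <- merge_instances(m1)
  expect_equal(m2$area_px, m1$area_px)
  expect_equal(m2$x, m1$x)

  # identical duplicates collapse to one
  dup <- dplyr::bind_rows(
    square_instance(5, 5, 20, id = 1L, score = 0.9),
    square_instance(5, 5, 20, id = 2L, score = 0.7))
  expect_equal(nrow(merge_instances(dup)), 1L)
})

test_that("tiled and untiled processing agree when shells fit within tiles", {
  sc <- clean_scene()
  cfg <- run_config(window = 256L, overlap = 64L)
  tiled <- segment_panel(sc$panel, cfg)
  untiled <- classify_by_elongation(
    merge_instances(segment_baseline(sc$panel$pixels, cfg)), cfg)
  expect_equal(nrow(tiled), nrow(untiled))
})

test_that("external predictions are validated against the panel frame", {
  sc <- clean_scene()
  ann <- sc$annotations
  got <- ingest_external_predictions(ann, sc$panel)
  expect_equal(nrow(got), nrow(ann$instances))

  # frame mismatch
  wrong <- shell_annotations(empty_instances(), 10, 10)
  expect_error(ingest_external_predictions(wrong, sc$panel),
               class = "shellcarbon_registration_error")

  # a 5 px speck below the 10 px floor is dropped with a warning
  speck <- instance_from_mask(
    {m <- matrix(FALSE, ann$height, ann$width); m[1:5, 3] <- TRUE; m},
    "barnacle", instance_id = 999L)
  with_speck <- shell_annotations(
    dplyr::bind_rows(ann$instances, speck), ann$width, ann$height)
  expect_warning(kept <- ingest_external_predictions(with_speck, sc$panel),
                 regexp = "999")
  expect_equal(nrow(kept), nrow(ann$instances))
})

test_that("instances outside the frame are rejected when the set is built", {
  bad <- square_instance(95, 95, 10, width = 110, height = 110)
  expect_error(shell_annotations(bad, 100, 100),   # extends to 105 > 100
               class = "shellcarbon_bounds_error")
})
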