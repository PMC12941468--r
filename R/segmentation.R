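# Sliding-window tiling, a classical baseline segmenter, and stitching of
# per-tile predictions back into panel coordinates.

#' Tile a large image into sliding windows
#'
#' Stride is `window - overlap`; the last tile on each axis is anchored to
#' the image edge so that every pixel is covered (which may locally increase
#' the effective overlap). An image smaller than the window yields a single
#' full-image tile.
#'
#' @param width,height image size in pixels (a `panel_image` may be passed
#'   as `width`).
#' @param window tile size in pixels.
#' @param overlap overlap between adjacent tiles in pixels.
#' @return tibble of tiles with 0-based `x0`, `y0`, `w`, `h`.
#' @export
tile_image <- function(width, height = NULL, window = 512L, overlap = 64L) {
  if (inherits(width, "panel_image")) {
    height <- width$height_px; width <- width$width_px
  }
  if (!(window > overlap && overlap >= 0)) {
    abort("need window > overlap >= 0", class = "shellcarbon_config_error")
  }
  axis_starts <- function(dim) {
    if (window >= dim) return(list(starts = 0L, size = dim))
    stride <- window - overlap
    s <- seq(0L, dim - window, by = stride)
    if (tail(s, 1L) != dim - window) s <- c(s, dim - window)
    list(starts = s, size = window)
  }
  ax <- axis_starts(width); ay <- axis_starts(height)
  tidyr::expand_grid(y0 = ay$starts, x0 = ax$starts) |>
    mutate(w = ax$size, h = ay$size) |>
    select("x0", "y0", "w", "h")
}

#' Classical baseline segmenter for one tile
#'
#' A deliberately simple stand-in for a learned instance segmenter, adequate
#' for clean scenes: the tile is flattened by subtracting a least-squares
#' linear illumination plane, thresholded by Otsu's method, opened to drop
#' speckle, and touching blobs are split by marker-based watershed on the
#' distance transform. Components below the minimum area are discarded.
#' Classes are assigned by elongation (min-area-rectangle aspect B/L below
#' `config$bivalve_aspect_max` means bivalve) and the confidence score is
#' the component's solidity (area over convex hull area).
#'
#' @param raster numeric matrix (grayscale tile, rows = y).
#' @param config a [run_config()].
#' @return instance table in tile coordinates (possibly empty).
#' @export
segment_baseline <- function(raster, config = run_config()) {
  h <- nrow(raster); w <- ncol(raster)
  # illumination flattening: remove the best-fit linear plane of the
  # background; the plane is fit on all pixels, which is adequate when
  # foreground cover is modest
  xs <- rep(seq_len(w), each = h) / w
  ys <- rep(seq_len(h), times = w) / h
  v <- as.vector(raster)
  plane <- lm.fit(cbind(1, xs, ys), v)
  flat <- matrix(v - plane$fitted.values + mean(v), h, w)
  img <- EBImage::Image(t(flat))            # EBImage dims are (x, y)
  th <- tryCatch(EBImage::otsu(img, range = range(flat)),
                 error = function(e) NA_real_)
  if (!is.finite(th)) return(empty_instances())
  binary <- img > th
  if (sum(binary) == 0 || sum(binary) == length(binary)) {
    return(empty_instances())
  }
  binary <- EBImage::opening(binary, EBImage::makeBrush(5, shape = "disc"))
  if (sum(binary) == 0) return(empty_instances())
  labels <- EBImage::watershed(EBImage::distmap(binary), tolerance = 1, ext = 1)
  lab <- t(EBImage::imageData(labels))       # back to rows = y
  rows <- list()
  for (id in setdiff(sort(unique(as.vector(lab))), 0L)) {
    m <- lab == id
    if (sum(m) < config$min_area_px) next
    inst <- instance_from_mask(m, class = "barnacle",
                               instance_id = length(rows) + 1L)
    dims <- tryCatch({
      idx <- which(inst$mask[[1L]], arr.ind = TRUE)
      moment_axes(inst$x + idx[, 2L] - 0.5, inst$y + idx[, 1L] - 0.5)
    }, shellcarbon_geometry_error = function(e) NULL)
    if (is.null(dims)) next
    aspect <- dims$short_px / dims$long_px
    inst$class <- if (aspect < config$bivalve_aspect_max) "bivalve" else "barnacle"
    inst$score <- component_solidity(inst)
    rows[[length(rows) + 1L]] <- inst
  }
  if (!length(rows)) return(empty_instances())
  out <- dplyr::bind_rows(rows)
  out$instance_id <- seq_len(nrow(out))
  out
}

component_solidity <- function(inst) {
  idx <- which(inst$mask[[1L]], arr.ind = TRUE)
  if (nrow(idx) < 3) return(1)
  pts <- cbind(idx[, 2L], idx[, 1L])
  hull <- pts[chull(pts), , drop = FALSE]
  n <- nrow(hull)
  if (n < 3) return(1)
  # shoelace + boundary correction to approximate the pixel-footprint hull
  area <- abs(sum(hull[, 1L] * hull[c(2:n, 1L), 2L] -
                  hull[c(2:n, 1L), 1L] * hull[, 2L])) / 2
  per <- sum(sqrt(rowSums((hull - hull[c(2:n, 1L), ])^2)))
  hull_area <- area + per / 2 + 1
  min(1, inst$area_px / hull_area)
}

#' Stitch per-tile predictions into panel coordinates
#'
#' Translates each tile's instances by its offset and fuses duplicates that
#' arise where tiles overlap: two instances are connected when their mask
#' IoU exceeds `merge_iou` or when the smaller mask is at least 80%
#' contained in the larger. Connected components of this graph are merged
#' transitively; the merged instance is the pixel union, takes the higher
#' score, and the class of its highest-scoring member.
#'
#' @param tile_instances list of instance tables, one per tile.
#' @param offsets tibble/data frame of tile origins (`x0`, `y0`), one row
#'   per tile (e.g. from [tile_image()]).
#' @param merge_iou mask IoU threshold for fusion.
#' @param containment containment fraction that also triggers fusion.
#' @return instance table in panel coordinates.
#' @export
merge_tile_predictions <- function(tile_instances, offsets, merge_iou = 0.5,
                                   containment = 0.8) {
  stopifnot(length(tile_instances) == nrow(offsets))
  all <- purrr::imap(tile_instances, function(inst, i) {
    translate_instances(inst, offsets$x0[i], offsets$y0[i])
  }) |> dplyr::bind_rows()
  merge_instances(all, merge_iou, containment)
}

#' Fuse duplicate instances within one coordinate frame
#'
#' @inheritParams merge_tile_predictions
#' @param instances instance table in a single frame.
#' @return instance table with duplicates fused; idempotent.
#' @export
merge_instances <- function(instances, merge_iou = 0.5, containment = 0.8) {
  n <- nrow(instances)
  if (n <= 1L) {
    if (n == 1L) instances$instance_id <- 1L
    return(instances)
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    a <- instances[i, ]
    for (j in (i + 1L):n) {
      b <- instances[j, ]
      if (a$x >= b$x + b$w || b$x >= a$x + a$w ||
          a$y >= b$y + b$h || b$y >= a$y + a$h) next
      if (mask_iou(a, b) > merge_iou || mask_containment(a, b) >= containment) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  groups <- vapply(seq_len(n), find, integer(1))
  out <- purrr::map(unique(groups), function(g) {
    members <- instances[groups == g, ]
    if (nrow(members) == 1L) return(members)
    x0 <- min(members$x); y0 <- min(members$y)
    x1 <- max(members$x + members$w); y1 <- max(members$y + members$h)
    m <- matrix(FALSE, nrow = y1 - y0, ncol = x1 - x0)
    for (k in seq_len(nrow(members))) {
      row <- members[k, ]
      rr <- (row$y - y0 + 1):(row$y - y0 + row$h)
      cc <- (row$x - x0 + 1):(row$x - x0 + row$w)
      m[rr, cc] <- m[rr, cc] | row$mask[[1L]]
    }
    best <- if (all(is.na(members$score))) 1L else which.max(members$score)
    tibble::tibble(
      instance_id = members$instance_id[1L],
      class = members$class[best],
      score = if (all(is.na(members$score))) NA_real_ else max(members$score, na.rm = TRUE),
      x = x0, y = y0, w = x1 - x0, h = y1 - y0,
      area_px = as.double(sum(m)), mask = list(m))
  }) |> dplyr::bind_rows()
  out$instance_id <- seq_len(nrow(out))
  out
}

#' Validate and ingest external model predictions
#'
#' Bridges predictions from an external instance-segmentation model (read
#' with [read_coco()]) into the pipeline: checks that the annotation frame
#' matches the panel raster, drops instances below the minimum area with a
#' warning, and passes the rest through unchanged.
#'
#' @param ann a [shell_annotations()] object of predictions.
#' @param panel the `panel_image` the predictions refer to.
#' @param min_area_px minimum instance area kept.
#' @return instance table in panel coordinates.
#' @export
ingest_external_predictions <- function(ann, panel, min_area_px = 10) {
  if (ann$width != panel$width_px || ann$height != panel$height_px) {
    abort(sprintf(
      "prediction frame %dx%d does not match the panel raster %dx%d",
      ann$width, ann$height, panel$width_px, panel$height_px),
      class = "shellcarbon_registration_error")
  }
  inst <- ann$instances
  small <- inst$area_px < min_area_px
  if (any(small)) {
    warn(sprintf("dropping %d instance(s) below %g px: %s",
                 sum(small), min_area_px,
                 paste(inst$instance_id[small], collapse = ", ")))
    inst <- inst[!small, ]
  }
  inst
}

#' Segment a whole panel with the baseline segmenter
#'
#' Tiles the panel, runs [segment_baseline()] per tile, stitches the results
#' with [merge_tile_predictions()], and re-applies the elongation
#' classification rule to the merged masks (a shell cut by a tile boundary
#' is classified from a fragment otherwise, and a crosswise half of an
#' elongated shell reads as near-circular).
#'
#' @param panel a `panel_image`.
#' @param config a [run_config()].
#' @return instance table in panel coordinates.
#' @export
segment_panel <- function(panel, config = run_config()) {
  tiles <- tile_image(panel, window = config$window, overlap = config$overlap)
  preds <- purrr::pmap(tiles, function(x0, y0, w, h) {
    segment_baseline(panel$pixels[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w),
                                  drop = FALSE], config)
  })
  merged <- merge_tile_predictions(preds, tiles, merge_iou = config$merge_iou)
  classify_by_elongation(merged, config)
}

#' Classify instances by mask elongation
#'
#' The baseline class rule: moment-ellipse aspect ratio B/L below
#' `config$bivalve_aspect_max` means bivalve, otherwise barnacle.
#'
#' @param instances instance table.
#' @param config a [run_config()].
#' @return the instance table with `class` reassigned.
#' @export
classify_by_elongation <- function(instances, config = run_config()) {
  for (i in seq_len(nrow(instances))) {
    row <- instances[i, ]
    ax <- tryCatch({
      idx <- which(row$mask[[1L]], arr.ind = TRUE)
      moment_axes(row$x + idx[, 2L] - 0.5, row$y + idx[, 1L] - 0.5)
    }, shellcarbon_geometry_error = function(e) NULL)
    if (is.null(ax)) next
    instances$class[i] <-
      if (ax$short_px / ax$long_px < config$bivalve_aspect_max) "bivalve"
      else "barnacle"
  }
  instances
}
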