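# Instance masks are stored bbox-cropped: each row of an instance table keeps
# its bounding box (x, y, w, h) in 0-based, half-open pixel coordinates
# (origin top-left, COCO convention) plus a logical matrix `mask` of dim
# c(h, w) whose [r, c] entry refers to pixel (x + c - 1, y + r - 1).

#' Create an empty instance table
#'
#' The instance table is the package's central tabular container: one row per
#' segmented organism, with the binary mask held bbox-cropped in a list
#' column. All coordinates are 0-based pixels with origin at the top-left,
#' and bounding boxes are half-open `(x, y, w, h)` as in COCO.
#'
#' @return A zero-row tibble with columns `instance_id`, `class`, `score`,
#'   `x`, `y`, `w`, `h`, `area_px`, `mask`.
#' @export
empty_instances <- function() {
  tibble::tibble(
    instance_id = integer(),
    class = character(),
    score = double(),
    x = double(), y = double(), w = double(), h = double(),
    area_px = double(),
    mask = list()
  )
}

#' Build one instance row from a full-frame logical mask
#'
#' @param mask_full logical matrix, `[row, col]` = `[y + 1, x + 1]`.
#' @param class class label.
#' @param score detection confidence in `[0, 1]`, or `NA` for ground truth.
#' @param instance_id integer id.
#' @return One-row instance tibble (see [empty_instances()]).
#' @export
instance_from_mask <- function(mask_full, class, score = NA_real_,
                               instance_id = 1L) {
  stopifnot(is.matrix(mask_full), is.logical(mask_full))
  idx <- which(mask_full, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    abort("instance mask is empty", class = "shellcarbon_mask_error")
  }
  r0 <- min(idx[, 1L]); r1 <- max(idx[, 1L])
  c0 <- min(idx[, 2L]); c1 <- max(idx[, 2L])
  m <- mask_full[r0:r1, c0:c1, drop = FALSE]
  tibble::tibble(
    instance_id = as.integer(instance_id),
    class = as.character(class),
    score = as.double(score),
    x = c0 - 1, y = r0 - 1,
    w = c1 - c0 + 1, h = r1 - r0 + 1,
    area_px = as.double(sum(m)),
    mask = list(m)
  )
}

# Recompute bbox/area from the cropped mask after an edit; trims empty margins.
retighten_instance <- function(row) {
  full_x <- row$x; full_y <- row$y
  m <- row$mask[[1L]]
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  r0 <- min(idx[, 1L]); r1 <- max(idx[, 1L])
  c0 <- min(idx[, 2L]); c1 <- max(idx[, 2L])
  row$mask[[1L]] <- m[r0:r1, c0:c1, drop = FALSE]
  row$x <- full_x + c0 - 1; row$y <- full_y + r0 - 1
  row$w <- c1 - c0 + 1; row$h <- r1 - r0 + 1
  row$area_px <- as.double(sum(row$mask[[1L]]))
  row
}

#' Expand an instance row back to a full-frame logical mask
#'
#' @param row one-row slice of an instance table.
#' @param width,height frame size in pixels.
#' @return logical matrix `height x width`.
#' @export
full_mask <- function(row, width, height) {
  out <- matrix(FALSE, nrow = height, ncol = width)
  rr <- (row$y + 1):(row$y + row$h)
  cc <- (row$x + 1):(row$x + row$w)
  if (min(rr) < 1 || max(rr) > height || min(cc) < 1 || max(cc) > width) {
    abort(
      sprintf("instance %s extends outside the %dx%d frame",
              row$instance_id, width, height),
      class = "shellcarbon_bounds_error"
    )
  }
  out[rr, cc] <- row$mask[[1L]]
  out
}

#' Union of all instance masks as one full-frame foreground mask
#'
#' @param instances instance table.
#' @param width,height frame size in pixels.
#' @return logical matrix `height x width`.
#' @export
union_mask <- function(instances, width, height) {
  out <- matrix(FALSE, nrow = height, ncol = width)
  for (i in seq_len(nrow(instances))) {
    row <- instances[i, ]
    rr <- (row$y + 1):(row$y + row$h)
    cc <- (row$x + 1):(row$x + row$w)
    out[rr, cc] <- out[rr, cc] | row$mask[[1L]]
  }
  out
}

# Pairwise mask overlap computed on the bbox intersection only.
mask_intersection_px <- function(a, b) {
  x0 <- max(a$x, b$x); y0 <- max(a$y, b$y)
  x1 <- min(a$x + a$w, b$x + b$w); y1 <- min(a$y + a$h, b$y + b$h)
  if (x1 <= x0 || y1 <= y0) return(0)
  sub <- function(row) {
    row$mask[[1L]][(y0 - row$y + 1):(y1 - row$y),
                   (x0 - row$x + 1):(x1 - row$x), drop = FALSE]
  }
  sum(sub(a) & sub(b))
}

#' Mask IoU between two instance rows
#'
#' @param a,b one-row slices of an instance table, same pixel frame.
#' @return intersection-over-union in `[0, 1]`.
#' @export
mask_iou <- function(a, b) {
  inter <- mask_intersection_px(a, b)
  if (inter == 0) return(0)
  inter / (a$area_px + b$area_px - inter)
}

# Fraction of the smaller mask covered by the intersection.
mask_containment <- function(a, b) {
  inter <- mask_intersection_px(a, b)
  if (inter == 0) return(0)
  inter / min(a$area_px, b$area_px)
}

#' Rasterize a polygon to a logical mask
#'
#' Even-odd scanline fill sampled at pixel centers `(x + 0.5, y + 0.5)`.
#' Vertices are in 0-based pixel coordinates measured from the image's
#' top-left corner (the LabelMe and COCO convention).
#'
#' @param xs,ys polygon vertex coordinates (closed implicitly).
#' @param width,height frame size in pixels.
#' @return logical matrix `height x width`.
#' @export
rasterize_polygon <- function(xs, ys, width, height) {
  n <- length(xs)
  stopifnot(n == length(ys))
  if (n < 3) {
    abort("polygon needs at least 3 vertices", class = "shellcarbon_bounds_error")
  }
  out <- matrix(FALSE, nrow = height, ncol = width)
  x2 <- c(xs[-1L], xs[1L]); y2 <- c(ys[-1L], ys[1L])
  ymin <- max(0L, floor(min(ys) - 0.5))
  ymax <- min(height - 1L, ceiling(max(ys)))
  for (yy in ymin:ymax) {
    yc <- yy + 0.5
    crosses <- ((ys <= yc) & (y2 > yc)) | ((y2 <= yc) & (ys > yc))
    if (!any(crosses)) next
    xi <- xs[crosses] + (yc - ys[crosses]) * (x2[crosses] - xs[crosses]) /
      (y2[crosses] - ys[crosses])
    xi <- sort(xi)
    for (k in seq(1L, length(xi) - 1L, by = 2L)) {
      # pixel centers x + 0.5 inside [xi[k], xi[k+1])
      c0 <- max(0L, ceiling(xi[k] - 0.5))
      c1 <- min(width - 1L, ceiling(xi[k + 1L] - 0.5) - 1L)
      if (c1 >= c0) out[yy + 1L, (c0 + 1L):(c1 + 1L)] <- TRUE
    }
  }
  out
}

# COCO uncompressed RLE: column-major pixel order, counts alternate starting
# with the number of background (0) pixels.
rle_encode <- function(mask_full) {
  v <- as.integer(mask_full)            # column-major by construction
  r <- rle(v)
  counts <- r$lengths
  if (r$values[1L] == 1L) counts <- c(0L, counts)
  list(counts = as.integer(counts), size = dim(mask_full))
}

rle_decode <- function(counts, height, width) {
  total <- height * width
  if (sum(counts) != total) {
    abort("RLE counts do not sum to the mask size",
          class = "shellcarbon_schema_error")
  }
  vals <- rep(rep(c(FALSE, TRUE), length.out = length(counts)), counts)
  matrix(vals, nrow = height, ncol = width)
}

#' Translate instances into another pixel frame
#'
#' @param instances instance table.
#' @param dx,dy offsets in pixels to add to every bounding box.
#' @return the translated instance table.
#' @export
translate_instances <- function(instances, dx, dy) {
  instances$x <- instances$x + dx
  instances$y <- instances$y + dy
  instances
}
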