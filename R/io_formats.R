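# Annotation sets couple an instance table to the pixel frame it lives in.

#' Construct an annotation set
#'
#' @param instances instance table (see [empty_instances()]).
#' @param width,height image size in pixels.
#' @param image_id identifier carried through to COCO output.
#' @return object of class `shell_annotations`.
#' @export
shell_annotations <- function(instances, width, height, image_id = 1L) {
  stopifnot(width > 0, height > 0)
  for (i in seq_len(nrow(instances))) {
    row <- instances[i, ]
    if (row$x < 0 || row$y < 0 || row$x + row$w > width ||
        row$y + row$h > height) {
      abort(
        sprintf("instance %s lies outside the %dx%d image",
                row$instance_id, as.integer(width), as.integer(height)),
        class = "shellcarbon_bounds_error"
      )
    }
  }
  structure(
    list(image_id = image_id, width = as.integer(width),
         height = as.integer(height), instances = instances),
    class = "shell_annotations"
  )
}

#' @export
print.shell_annotations <- function(x, ...) {
  cat(sprintf("<shell_annotations> image %s (%d x %d px), %d instance(s)\n",
              x$image_id, x$width, x$height, nrow(x$instances)))
  if (nrow(x$instances)) print(table(x$instances$class))
  invisible(x)
}

#' @method tidy shell_annotations
#' @export
tidy.shell_annotations <- function(x, ...) {
  dplyr::select(x$instances, -"mask")
}

#' Run configuration
#'
#' Bundles the tunable knobs of the quantification pipeline. Window and
#' overlap control the sliding-window tiler; `merge_iou` is the mask-IoU
#' threshold above which stitched tile predictions are fused; `match_iou`
#' is the instance-matching threshold for precision/recall; `min_area_px`
#' drops speckle components before they can enter carbon totals;
#' `small_area_px2` is the COCO-style "small object" cut-off used by the
#' small-object recall metric.
#'
#' @param window tile size in pixels (default 512, the patch size used for
#'   patch-wise inference on high-resolution panel images).
#' @param overlap tile overlap in pixels; must be smaller than `window`.
#' @param merge_iou mask IoU above which two stitched instances are merged.
#' @param match_iou IoU threshold for instance matching in evaluation.
#' @param min_area_px minimum instance area kept, in pixels.
#' @param small_area_px2 ground-truth area below which an object counts as
#'   small (default 32^2 px, the COCO convention).
#' @param bivalve_aspect_max baseline classifier rule: components whose
#'   min-area-rectangle aspect ratio B/L falls below this value are called
#'   bivalves, the rest barnacles.
#' @param seed integer seed threaded to stochastic stages.
#' @return a list of class `run_config`.
#' @export
run_config <- function(window = 512L, overlap = 64L, merge_iou = 0.5,
                       match_iou = 0.5, min_area_px = 10, small_area_px2 = 1024,
                       bivalve_aspect_max = 0.78, seed = 1L) {
  if (!(window > overlap && overlap >= 0)) {
    abort("need window > overlap >= 0", class = "shellcarbon_config_error")
  }
  for (v in c(merge_iou, match_iou)) {
    if (!(v > 0 && v < 1)) {
      abort("IoU thresholds must lie in (0, 1)", class = "shellcarbon_config_error")
    }
  }
  structure(
    list(window = as.integer(window), overlap = as.integer(overlap),
         merge_iou = merge_iou, match_iou = match_iou,
         min_area_px = min_area_px, small_area_px2 = small_area_px2,
         bivalve_aspect_max = bivalve_aspect_max, seed = as.integer(seed)),
    class = "run_config"
  )
}

# ---------------------------------------------------------------------------
# LabelMe

#' Read LabelMe polygon annotations
#'
#' Parses a LabelMe JSON document (the `shapes`/`points` schema produced by
#' the LabelMe annotation tool) into an annotation set. Polygon labels are
#' mapped through `aliases` (e.g. `c(mussel = "bivalve")`) and then checked
#' against `allowed`; unknown labels raise an error unless `lenient = TRUE`,
#' in which case they are reported and dropped.
#'
#' @param text JSON text, or a file path to a `.json` file.
#' @param aliases named character vector mapping raw labels to canonical ones.
#' @param allowed canonical class labels accepted into the set.
#' @param lenient demote unknown-label errors to warnings.
#' @return a [shell_annotations()] object.
#' @export
read_labelme <- function(text, aliases = character(),
                         allowed = c("barnacle", "bivalve"),
                         lenient = FALSE) {
  doc <- parse_json_document(text)
  if (is.null(doc$imageWidth) || is.null(doc$imageHeight)) {
    abort("LabelMe document lacks imageWidth/imageHeight",
          class = "shellcarbon_schema_error")
  }
  width <- as.integer(doc$imageWidth)
  height <- as.integer(doc$imageHeight)
  shapes <- doc$shapes
  if (is.null(shapes)) {
    abort("LabelMe document has no `shapes` field",
          class = "shellcarbon_schema_error")
  }
  rows <- list()
  next_id <- 1L
  for (k in seq_along(shapes)) {
    sh <- shapes[[k]]
    label <- as.character(sh$label)
    if (label %in% names(aliases)) label <- unname(aliases[[label]])
    if (!label %in% allowed) {
      msg <- sprintf("shape %d has unknown label '%s'", k, sh$label)
      if (lenient) { warn(msg); next }
      abort(msg, class = "shellcarbon_label_error")
    }
    pts <- sh$points
    if (is.list(pts)) pts <- do.call(rbind, lapply(pts, unlist))
    pts <- matrix(as.numeric(pts), ncol = 2)
    if (nrow(pts) < 3) {
      abort(sprintf("shape %d ('%s') has fewer than 3 points", k, label),
            class = "shellcarbon_bounds_error")
    }
    if (min(pts) < 0 || max(pts[, 1]) > width || max(pts[, 2]) > height) {
      abort(sprintf("shape %d ('%s') extends outside the image", k, label),
            class = "shellcarbon_bounds_error")
    }
    m <- rasterize_polygon(pts[, 1], pts[, 2], width, height)
    rows[[length(rows) + 1L]] <-
      instance_from_mask(m, class = label, instance_id = next_id)
    next_id <- next_id + 1L
  }
  inst <- if (length(rows)) dplyr::bind_rows(rows) else empty_instances()
  shell_annotations(inst, width, height,
                    image_id = doc$imagePath %||% 1L)
}

# ---------------------------------------------------------------------------
# COCO

#' Read COCO instance-segmentation annotations
#'
#' Accepts polygon segmentations and uncompressed run-length encodings
#' (`counts` as an integer list). Predictions (a bare annotation array from a
#' detector) can be read by supplying the accompanying image size.
#'
#' @param text JSON text or file path.
#' @param image_id which image of a multi-image document to extract.
#' @return a [shell_annotations()] object.
#' @export
read_coco <- function(text, image_id = NULL) {
  doc <- parse_json_document(text)
  for (f in c("images", "annotations", "categories")) {
    if (is.null(doc[[f]])) {
      abort(sprintf("COCO document lacks `%s`", f),
            class = "shellcarbon_schema_error")
    }
  }
  imgs <- doc$images
  if (is.null(image_id)) image_id <- imgs[[1L]]$id
  img <- NULL
  for (im in imgs) if (identical(im$id, image_id)) img <- im
  if (is.null(img)) {
    abort(sprintf("image id %s not present", image_id),
          class = "shellcarbon_schema_error")
  }
  width <- as.integer(img$width); height <- as.integer(img$height)
  cats <- setNames(
    vapply(doc$categories, function(x) as.character(x$name), character(1)),
    vapply(doc$categories, function(x) as.character(x$id), character(1))
  )
  rows <- list()
  for (an in doc$annotations) {
    if (!identical(an$image_id, image_id)) next
    cls <- cats[[as.character(an$category_id)]]
    if (is.null(cls)) {
      abort(sprintf("annotation %s references unknown category %s",
                    an$id %||% "?", an$category_id),
            class = "shellcarbon_schema_error")
    }
    seg <- an$segmentation
    if (!is.null(seg$counts)) {
      m <- rle_decode(as.integer(unlist(seg$counts)),
                      height = seg$size[[1L]], width = seg$size[[2L]])
      if (nrow(m) != height || ncol(m) != width) {
        abort(sprintf("annotation %s RLE size disagrees with the image",
                      an$id %||% "?"), class = "shellcarbon_bounds_error")
      }
    } else {
      m <- matrix(FALSE, height, width)
      polys <- if (is.list(seg)) seg else list(seg)
      for (p in polys) {
        p <- as.numeric(unlist(p))
        xs <- p[seq(1, length(p), 2)]; ys <- p[seq(2, length(p), 2)]
        if (length(xs) < 3) {
          abort(sprintf("annotation %s polygon has fewer than 3 vertices",
                        an$id %||% "?"), class = "shellcarbon_bounds_error")
        }
        if (min(p) < 0 || max(xs) > width || max(ys) > height) {
          abort(sprintf("annotation %s polygon outside image", an$id %||% "?"),
                class = "shellcarbon_bounds_error")
        }
        m <- m | rasterize_polygon(xs, ys, width, height)
      }
    }
    if (!any(m)) next
    row <- instance_from_mask(m, class = cls,
                              score = as.double(an$score %||% NA_real_),
                              instance_id = an$id %||% (length(rows) + 1L))
    rows[[length(rows) + 1L]] <- row
  }
  inst <- if (length(rows)) dplyr::bind_rows(rows) else empty_instances()
  shell_annotations(inst, width, height, image_id = image_id)
}

#' Write an annotation set as COCO JSON
#'
#' Masks are emitted as uncompressed column-major run-length encodings, which
#' round-trip pixel-exactly through [read_coco()].
#'
#' @param ann a [shell_annotations()] object.
#' @param path optional file to write; when `NULL` the JSON text is returned.
#' @return JSON text (invisibly when `path` is given).
#' @export
write_coco <- function(ann, path = NULL) {
  cats <- sort(unique(ann$instances$class))
  if (length(cats) == 0L) cats <- c("barnacle", "bivalve")
  cat_id <- setNames(seq_along(cats), cats)
  annotations <- lapply(seq_len(nrow(ann$instances)), function(i) {
    row <- ann$instances[i, ]
    rle <- rle_encode(full_mask(row, ann$width, ann$height))
    out <- list(
      id = row$instance_id,
      image_id = ann$image_id,
      category_id = unname(cat_id[[row$class]]),
      segmentation = list(size = c(ann$height, ann$width),
                          counts = rle$counts),
      bbox = c(row$x, row$y, row$w, row$h),
      area = row$area_px,
      iscrowd = 0L
    )
    if (!is.na(row$score)) out$score <- row$score
    out
  })
  doc <- list(
    images = list(list(id = ann$image_id, width = ann$width,
                       height = ann$height)),
    annotations = annotations,
    categories = lapply(cats, function(nm)
      list(id = unname(cat_id[[nm]]), name = nm, supercategory = "shell"))
  )
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

# ---------------------------------------------------------------------------
# Panel images

#' Load a panel photograph with its physical size
#'
#' Reads a PNG/TIFF/JPEG image and registers it to the physical panel it
#' depicts: the image frame is assumed to coincide with the panel, and the
#' pixel scale is the mean of the two axis ratios. When the axis scales
#' disagree by more than 2% a warning flags the anisotropy.
#'
#' @param path image file path, or a numeric matrix/array already in memory
#'   (grayscale `height x width`, values in `[0, 1]`).
#' @param panel_width_cm,panel_height_cm physical panel dimensions.
#' @param meta optional list of panel metadata (e.g. `group`, `date`,
#'   `temperature_c`).
#' @return a `panel_image` object.
#' @export
load_panel <- function(path, panel_width_cm, panel_height_cm, meta = list()) {
  if (!(panel_width_cm > 0 && panel_height_cm > 0)) {
    abort("panel dimensions must be positive", class = "shellcarbon_config_error")
  }
  px <- if (is.character(path)) read_image_file(path) else path
  if (length(dim(px)) == 3L) px <- rowMeans(px, dims = 2L)  # luminance-ish
  if (!is.matrix(px) || !nrow(px) || !ncol(px)) {
    abort("image is empty or unreadable", class = "shellcarbon_io_error")
  }
  sx <- ncol(px) / panel_width_cm
  sy <- nrow(px) / panel_height_cm
  aniso <- abs(sx - sy) / max(sx, sy)
  if (aniso > 0.02) {
    warn(sprintf(
      "axis pixel scales disagree by %.1f%% (x: %.2f, y: %.2f px/cm); using the mean",
      100 * aniso, sx, sy))
  }
  structure(
    list(pixels = px, width_px = ncol(px), height_px = nrow(px),
         panel_width_cm = panel_width_cm, panel_height_cm = panel_height_cm,
         scale_px_per_cm = mean(c(sx, sy)), meta = meta),
    class = "panel_image"
  )
}

#' @export
print.panel_image <- function(x, ...) {
  cat(sprintf(
    "<panel_image> %d x %d px on a %.4g x %.4g cm panel (%.4g px/cm)\n",
    x$width_px, x$height_px, x$panel_width_cm, x$panel_height_cm,
    x$scale_px_per_cm))
  invisible(x)
}

read_image_file <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read image '%s'", path), class = "shellcarbon_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    jpg = , jpeg = as.array(EBImage::readImage(path)),
    abort(sprintf("unsupported image format '%s'", ext),
          class = "shellcarbon_io_error")
  )
  if (ext %in% c("jpg", "jpeg")) {
    # EBImage stores x as the first dimension
    px <- if (length(dim(px)) == 3L) aperm(px, c(2L, 1L, 3L)) else t(px)
  }
  px
}

#' Write a grayscale panel raster to PNG
#'
#' @param panel a `panel_image` or a numeric matrix in `[0, 1]`.
#' @param path output file path.
#' @export
write_panel_png <- function(panel, path) {
  px <- if (inherits(panel, "panel_image")) panel$pixels else panel
  png::writePNG(pmin(pmax(px, 0), 1), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# CSV report

report_columns <- c("no", "species", "L_mm", "B_mm", "area_cm2",
                    "dry_weight_g", "carbon_g")

#' Write a panel carbon report as CSV
#'
#' One row per individual (number, species, projected length and width in
#' mm, attachment area in cm^2, shell dry weight in g, carbonate carbon in
#' g), followed by a totals row. Numeric columns are printed at 4 decimal
#' places.
#'
#' @param report a `panel_carbon_report` (see [panel_report()]).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_report_csv <- function(report, path) {
  rec <- report$records
  df <- data.frame(
    no = if (nrow(rec)) seq_len(nrow(rec)) else integer(),
    species = rec$species,
    L_mm = round(rec$L_mm, 4), B_mm = round(rec$B_mm, 4),
    area_cm2 = round(rec$area_cm2, 4),
    dry_weight_g = round(rec$dry_weight_g, 4),
    carbon_g = round(rec$carbon_g, 4)
  )
  totals <- data.frame(
    no = NA_integer_, species = "Total",
    L_mm = NA_real_, B_mm = NA_real_,
    area_cm2 = round(sum(df$area_cm2), 4),
    dry_weight_g = round(sum(df$dry_weight_g), 4),
    carbon_g = round(sum(df$carbon_g), 4)
  )
  out <- rbind(df, totals)
  write.csv(format(out, nsmall = 4, trim = TRUE), path, row.names = FALSE,
            quote = FALSE, na = "")
  invisible(path)
}

#' Read back a CSV carbon report
#'
#' @param path CSV path written by [write_report_csv()].
#' @return list with `records` (tibble, data rows) and `totals` (one row).
#' @export
read_report_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  is_total <- df$species == "Total"
  list(records = tibble::as_tibble(df[!is_total, ]),
       totals = tibble::as_tibble(df[is_total, ]))
}

# ---------------------------------------------------------------------------

parse_json_document <- function(text) {
  src <- if (length(text) == 1L && !grepl("[{\\[]", substr(text, 1, 1)) &&
             file.exists(text)) text else paste(text, collapse = "\n")
  tryCatch(
    jsonlite::fromJSON(src, simplifyVector = FALSE),
    error = function(e) abort(paste0("JSON parse error: ", conditionMessage(e)),
                              class = "shellcarbon_parse_error")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
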