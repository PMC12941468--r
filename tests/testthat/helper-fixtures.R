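# Shared fixtures, all built in code.

# square mask instance: side `s` px with top-left corner at 0-based (x, y)
square_instance <- function(x, y, s, class = "barnacle", score = NA_real_,
                            id = 1L, width = 100L, height = 100L) {
  m <- matrix(FALSE, height, width)
  m[(y + 1):(y + s), (x + 1):(x + s)] <- TRUE
  instance_from_mask(m, class = class, score = score, instance_id = id)
}

# axis-aligned ellipse mask in a full frame, semi-axes in px
ellipse_instance <- function(cx, cy, a, b, theta = 0, class = "barnacle",
                             score = NA_real_, id = 1L,
                             width = 200L, height = 200L) {
  xs <- (0:(width - 1)) + 0.5
  ys <- (0:(height - 1)) + 0.5
  dx <- outer(rep(1, height), xs - cx)
  dy <- outer(ys - cy, rep(1, width))
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  instance_from_mask((u^2 + v^2) <= 1, class = class, score = score,
                     instance_id = id)
}

labelme_doc <- function(shapes, width = 120L, height = 100L) {
  jsonlite::toJSON(list(imageWidth = width, imageHeight = height,
                        imagePath = "panel.png", shapes = shapes),
                   auto_unbox = TRUE)
}

labelme_shape <- function(label, pts) {
  list(label = label, points = lapply(seq_len(nrow(pts)),
                                      function(i) pts[i, ]))
}

# a clean rendered scene shared by segmentation tests (built once per run)
clean_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- scenario_spec(n_barnacle = 12, n_bivalve = 4,
                            scale_px_per_cm = 20, noise_sd = 0,
                            illumination = 0, texture = 0)
      cache <<- simulate_scene(spec, seed = 42)
    }
    cache
  }
})
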