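# Synthetic panel scenes with pixel-perfect ground truth.
#
# Shell footprints are ellipses (convex, parametric, analytically known), so
# every rendered instance carries its exact mask and its true projected
# length/width. Barnacles are near-circular with a radial ridge texture;
# bivalves are elongated with an axial shading gradient. Realism is
# deliberately geometric, not photographic: the quantities under test are
# masks, dimensions and carbon, not appearance.

#' Scenario specification for the scene generator
#'
#' Sizes follow a truncated lognormal law per class (positive, right-skewed,
#' the usual shape of fouling size distributions); widths are the length
#' times a uniform aspect-ratio draw. Defaults emulate a settled community
#' of adult calcifiers — barnacles around 1.2 cm basal diameter, bivalves
#' around 2.2 cm — with a lower size floor representing the annotatable
#' detection limit: the benchmark targets the medium-to-large individuals
#' that dominate panel carbon storage, and below the floor a binary mask at
#' bench resolution no longer pins down shell axes to the few-percent level
#' the downstream dimension checks rely on.
#'
#' @param panel_width_cm,panel_height_cm physical panel size (default the
#'   25 x 35 cm test panel).
#' @param scale_px_per_cm rendering resolution.
#' @param n_barnacle,n_bivalve instance counts to attempt.
#' @param barnacle_median_L_mm,bivalve_median_L_mm median projected lengths.
#' @param barnacle_gsd,bivalve_gsd geometric standard deviations of length.
#' @param barnacle_min_L_mm,bivalve_min_L_mm lower truncation of the size
#'   law (annotatable-size floor).
#' @param barnacle_aspect,bivalve_aspect B/L aspect-ratio ranges.
#' @param max_overlap maximum tolerated pairwise mask overlap, as a fraction
#'   of the smaller mask (0 = disjoint shells).
#' @param illumination amplitude of the linear illumination gradient
#'   (fraction of full scale across the panel).
#' @param noise_sd additive Gaussian pixel noise SD.
#' @param texture amplitude of the smooth background texture (0 = flat).
#' @param max_tries placement attempts per shell before giving up.
#' @return list of class `scenario_spec`.
#' @export
scenario_spec <- function(panel_width_cm = 25, panel_height_cm = 35,
                          scale_px_per_cm = 40,
                          n_barnacle = 45, n_bivalve = 10,
                          barnacle_median_L_mm = 12, barnacle_gsd = 1.3,
                          bivalve_median_L_mm = 22, bivalve_gsd = 1.4,
                          barnacle_min_L_mm = 6, bivalve_min_L_mm = 8,
                          barnacle_aspect = c(0.85, 1.00),
                          bivalve_aspect = c(0.50, 0.72),
                          max_overlap = 0, illumination = 0.10,
                          noise_sd = 0.02, texture = 0.02,
                          max_tries = 200L) {
  stopifnot(n_barnacle >= 0, n_bivalve >= 0,
            max_overlap >= 0, max_overlap < 1,
            all(barnacle_aspect > 0), all(barnacle_aspect <= 1),
            all(bivalve_aspect > 0), all(bivalve_aspect <= 1))
  structure(
    list(panel_width_cm = panel_width_cm, panel_height_cm = panel_height_cm,
         scale_px_per_cm = scale_px_per_cm,
         n_barnacle = n_barnacle, n_bivalve = n_bivalve,
         barnacle_median_L_mm = barnacle_median_L_mm,
         barnacle_gsd = barnacle_gsd,
         bivalve_median_L_mm = bivalve_median_L_mm, bivalve_gsd = bivalve_gsd,
         barnacle_min_L_mm = barnacle_min_L_mm,
         bivalve_min_L_mm = bivalve_min_L_mm,
         barnacle_aspect = barnacle_aspect, bivalve_aspect = bivalve_aspect,
         max_overlap = max_overlap, illumination = illumination,
         noise_sd = noise_sd, texture = texture,
         max_tries = as.integer(max_tries)),
    class = "scenario_spec"
  )
}

# lognormal truncated below at `lo` (resampling)
rtrunc_lnorm <- function(n, median, gsd, lo) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rlnorm(n, log(median), log(gsd))
    out <- c(out, x[x >= lo])
  }
  out[seq_len(n)]
}

# Cropped ellipse footprint at pixel centers; returns an instance-row-like
# list with bbox and mask, or NULL if nothing rasterizes.
ellipse_mask <- function(cx, cy, a_px, b_px, theta, width, height) {
  ct <- cos(theta); st <- sin(theta)
  ex <- sqrt((a_px * ct)^2 + (b_px * st)^2)
  ey <- sqrt((a_px * st)^2 + (b_px * ct)^2)
  x0 <- max(0L, floor(cx - ex)); x1 <- min(width - 1L, ceiling(cx + ex))
  y0 <- max(0L, floor(cy - ey)); y1 <- min(height - 1L, ceiling(cy + ey))
  if (x1 < x0 || y1 < y0) return(NULL)
  xs <- (x0:x1) + 0.5; ys <- (y0:y1) + 0.5
  dx <- outer(ys * 0, xs - cx, `+`)          # rows = y, cols = x
  dy <- outer(ys - cy, xs * 0, `+`)
  u <- (dx * ct + dy * st) / a_px
  v <- (-dx * st + dy * ct) / b_px
  m <- (u * u + v * v) <= 1
  if (!any(m)) return(NULL)
  idx <- which(m, arr.ind = TRUE)
  r0 <- min(idx[, 1L]); r1 <- max(idx[, 1L])
  c0 <- min(idx[, 2L]); c1 <- max(idx[, 2L])
  list(x = x0 + c0 - 1, y = y0 + r0 - 1,
       w = c1 - c0 + 1, h = r1 - r0 + 1,
       mask = m[r0:r1, c0:c1, drop = FALSE])
}

#' Sample a shell population onto a panel (geometry only)
#'
#' Dart-throwing placement: each candidate position is rejected when its
#' mask overlap with any accepted shell exceeds `spec$max_overlap` (as a
#' fraction of the smaller mask). Shells are kept fully inside the panel.
#' Fully deterministic for a fixed seed. If a shell cannot be placed within
#' `spec$max_tries` attempts a warning reports the achieved count.
#'
#' @param spec a [scenario_spec()].
#' @param seed integer seed.
#' @return instance table with extra ground-truth columns `cx`, `cy`,
#'   `theta`, `L_mm`, `B_mm`.
#' @export
sample_population <- function(spec, seed = 1L) {
  set.seed(seed)
  width <- round(spec$panel_width_cm * spec$scale_px_per_cm)
  height <- round(spec$panel_height_cm * spec$scale_px_per_cm)
  classes <- c(rep("bivalve", spec$n_bivalve),   # large shells placed first
               rep("barnacle", spec$n_barnacle))
  rows <- list()
  placed <- 0L
  for (k in seq_along(classes)) {
    cls <- classes[k]
    med <- if (cls == "barnacle") spec$barnacle_median_L_mm else spec$bivalve_median_L_mm
    gsd <- if (cls == "barnacle") spec$barnacle_gsd else spec$bivalve_gsd
    lo <- if (cls == "barnacle") spec$barnacle_min_L_mm else spec$bivalve_min_L_mm
    asp <- if (cls == "barnacle") spec$barnacle_aspect else spec$bivalve_aspect
    ok <- FALSE
    for (try in seq_len(spec$max_tries)) {
      L_mm <- rtrunc_lnorm(1, med, gsd, lo)
      B_mm <- L_mm * runif(1, asp[1L], asp[2L])
      a <- L_mm / 10 * spec$scale_px_per_cm / 2
      b <- B_mm / 10 * spec$scale_px_per_cm / 2
      theta <- runif(1, 0, pi)
      ext <- max(a, b) + 1
      if (2 * ext >= min(width, height)) next
      cx <- runif(1, ext, width - ext)
      cy <- runif(1, ext, height - ext)
      em <- ellipse_mask(cx, cy, a, b, theta, width, height)
      if (is.null(em)) next
      cand <- tibble::tibble(
        instance_id = placed + 1L, class = cls, score = NA_real_,
        x = em$x, y = em$y, w = em$w, h = em$h,
        area_px = as.double(sum(em$mask)), mask = list(em$mask),
        cx = cx, cy = cy, theta = theta, L_mm = L_mm, B_mm = B_mm)
      clash <- FALSE
      for (r in rows) {
        if (mask_containment(cand, r) > spec$max_overlap) { clash <- TRUE; break }
      }
      if (!clash) {
        placed <- placed + 1L
        rows[[placed]] <- cand
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      warn(sprintf("placement failed for a %s after %d tries; population has %d of %d shells",
                   cls, spec$max_tries, placed, length(classes)))
    }
  }
  if (placed == 0L) {
    out <- empty_instances()
    out$cx <- out$cy <- out$theta <- out$L_mm <- out$B_mm <- double()
    return(out)
  }
  dplyr::bind_rows(rows)
}

#' Render a sampled population into a panel image
#'
#' Background (optionally textured), linear illumination gradient across the
#' panel width, per-class shell shading, and additive Gaussian noise. The
#' annotation masks are the exact rendered footprints.
#'
#' @param population output of [sample_population()].
#' @param spec the [scenario_spec()] used to sample it.
#' @param seed seed for texture, shading jitter and noise.
#' @return list with `panel` (a `panel_image`), `annotations`
#'   (a [shell_annotations()]) and `truth` (the population without masks).
#' @export
render_scene <- function(population, spec, seed = 1L) {
  set.seed(seed + 1L)
  width <- round(spec$panel_width_cm * spec$scale_px_per_cm)
  height <- round(spec$panel_height_cm * spec$scale_px_per_cm)
  img <- matrix(0.35, nrow = height, ncol = width)
  if (spec$texture > 0) {
    xs <- seq_len(width) / width; ys <- seq_len(height) / height
    for (k in 1:3) {
      fx <- runif(1, 2, 9); fy <- runif(1, 2, 9); ph <- runif(2, 0, 2 * pi)
      img <- img + spec$texture / 3 *
        outer(sin(2 * pi * fy * ys + ph[2L]), sin(2 * pi * fx * xs + ph[1L]))
    }
  }
  if (spec$illumination > 0) {
    ramp <- spec$illumination * (2 * (seq_len(width) - 1) / max(1, width - 1) - 1)
    img <- img + matrix(ramp, nrow = height, ncol = width, byrow = TRUE)
  }
  for (i in seq_len(nrow(population))) {
    row <- population[i, ]
    m <- row$mask[[1L]]
    rr <- (row$y + 1):(row$y + row$h)
    cc <- (row$x + 1):(row$x + row$w)
    xs <- (row$x + seq_len(row$w) - 0.5)
    ys <- (row$y + seq_len(row$h) - 0.5)
    dx <- outer(ys * 0, xs - row$cx, `+`)
    dy <- outer(ys - row$cy, xs * 0, `+`)
    base <- if (row$class == "barnacle") 0.72 else 0.60
    base <- base + rnorm(1, 0, 0.02)
    shade <- if (row$class == "barnacle") {
      phi <- atan2(dy, dx)
      0.05 * cos(8 * phi)                       # radial ridges
    } else {
      u <- dx * cos(row$theta) + dy * sin(row$theta)
      0.06 * u / max(1e-9, max(abs(u)))         # axial gradient
    }
    patch <- img[rr, cc]
    patch[m] <- (base + shade)[m]
    img[rr, cc] <- patch
  }
  if (spec$noise_sd > 0) {
    img <- img + matrix(rnorm(height * width, 0, spec$noise_sd), height, width)
  }
  img <- pmin(pmax(img, 0), 1)
  panel <- load_panel(img, spec$panel_width_cm, spec$panel_height_cm)
  ann <- shell_annotations(
    dplyr::select(population, dplyr::all_of(names(empty_instances()))),
    width, height)
  truth <- dplyr::select(population, -"mask")
  list(panel = panel, annotations = ann, truth = truth)
}

#' Sample and render a scene in one call
#'
#' @inheritParams render_scene
#' @param spec a [scenario_spec()].
#' @param seed single seed for both placement and rendering.
#' @return as [render_scene()].
#' @export
simulate_scene <- function(spec, seed = 1L) {
  pop <- sample_population(spec, seed)
  render_scene(pop, spec, seed)
}

#' Synthetic allometric calibration samples
#'
#' Draws shell lengths from a lognormal size law, widths from a uniform
#' aspect range, and weights from the allometric model with multiplicative
#' lognormal noise of coefficient of variation `noise_cv` (meanlog 0, so the
#' noise multiplier has mean `exp(sigma^2 / 2)` with
#' `sigma^2 = log(1 + noise_cv^2)`).
#'
#' @param params one-row registry tibble supplying alpha, beta, valve factor.
#' @param n number of samples (>= 2).
#' @param noise_cv coefficient of variation of the weight noise (0 = exact).
#' @param seed integer seed.
#' @param median_L_mm,gsd,aspect size-law parameters.
#' @return tibble with `L_mm`, `B_mm`, `area_cm2`, `W_g`.
#' @export
generate_allometric_samples <- function(params, n, noise_cv = 0, seed = 1L,
                                        median_L_mm = 6, gsd = 1.6,
                                        aspect = c(0.6, 0.95)) {
  stopifnot(n >= 2, noise_cv >= 0)
  set.seed(seed)
  L <- rlnorm(n, log(median_L_mm), log(gsd))
  B <- L * runif(n, aspect[1L], aspect[2L])
  A <- attachment_area_cm2(L, B)
  W <- predict_dry_weight(A, params)
  if (noise_cv > 0) {
    sigma <- sqrt(log(1 + noise_cv^2))
    W <- W * rlnorm(n, 0, sigma)
  }
  tibble::tibble(L_mm = L, B_mm = B, area_cm2 = A, W_g = W)
}
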