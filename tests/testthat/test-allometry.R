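test_that("the built-in registry carries the published species parameters", {
  reg <- builtin_params()
  barn <- species_params(reg, "barnacle")
  biv <- species_params(reg, "bivalve")
  expect_equal(barn$beta, 1.60845)
  expect_equal(barn$alpha, 0.1597331)
  expect_equal(barn$carbon_fraction, 0.1207)
  expect_equal(biv$carbon_fraction, 0.1214)
  expect_equal(biv$valve_factor, 2L)
  expect_error(species_params(reg, "oyster"),
               class = "shellcarbon_lookup_error")
  # overrides apply without disturbing other fields
  reg2 <- builtin_params(list(barnacle = list(alpha = 0.2)))
  expect_equal(species_params(reg2, "barnacle")$alpha, 0.2)
  expect_equal(species_params(reg2, "barnacle")$beta, 1.60845)
})

test_that("dry-weight predictions reproduce the worked-example rows", {
  reg <- builtin_params()
  barn <- species_params(reg, "barnacle")
  biv <- species_params(reg, "bivalve")
  expect_equal(round(predict_dry_weight(0.2814, barn), 4), 0.0208)
  expect_equal(round(predict_dry_weight(0.3778, biv), 4), 0.0104)
})

test_that("the two-valve convention is what reproduces every bivalve row", {
  # brute force valve_factor over {1, 2} against all printed bivalve rows
  we <- worked_example()
  biv_rows <- we[we$species == "bivalve", ]
  biv <- species_params(builtin_params(), "bivalve")
  for (vf in c(1L, 2L)) {
    p <- biv
    p$valve_factor <- vf
    pred <- round(predict_dry_weight(biv_rows$area_cm2, p), 4)
    if (vf == 2L) {
      expect_equal(pred, biv_rows$dry_weight_g, tolerance = 5e-4)
    } else {
      expect_false(any(abs(pred - biv_rows$dry_weight_g) < 5e-4))
    }
  }
})

test_that("prediction obeys power-law algebra", {
  p <- species_params(builtin_params(), "bivalve")
  A <- c(0.1, 0.7, 2.3)
  expect_equal(predict_dry_weight(A, p) / (p$valve_factor * p$alpha),
               A^p$beta)
  # scaling all areas by c multiplies weights by c^beta
  expect_equal(predict_dry_weight(3 * A, p),
               3^p$beta * predict_dry_weight(A, p))
  # strictly increasing
  expect_true(all(diff(predict_dry_weight(A, p)) > 0))
})

test_that("noiseless samples recover alpha and beta to 6 significant digits", {
  barn <- species_params(builtin_params(), "barnacle")
  samples <- generate_allometric_samples(barn, n = 50, noise_cv = 0, seed = 2)
  fit <- fit_allometric(samples, valve_factor = 1L)
  expect_equal(signif(fit$params$alpha, 6), signif(barn$alpha, 6))
  expect_equal(signif(fit$params$beta, 6), signif(barn$beta, 6))
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  biv <- species_params(builtin_params(), "bivalve")
  s2 <- generate_allometric_samples(biv, n = 50, noise_cv = 0, seed = 3)
  fit2 <- fit_allometric(s2, valve_factor = 2L, species = "bivalve")
  expect_equal(signif(fit2$params$alpha, 6), signif(biv$alpha, 6))
  expect_equal(signif(fit2$params$beta, 6), signif(biv$beta, 6))
})

test_that("beta is recovered within 0.1 under 15% weight noise", {
  barn <- species_params(builtin_params(), "barnacle")
  for (seed in 1:20) {
    samples <- generate_allometric_samples(barn, n = 200, noise_cv = 0.15,
                                           seed = seed)
    fit <- fit_allometric(samples, valve_factor = 1L)
    expect_lt(abs(fit$params$beta - barn$beta), 0.1)
  }
})

test_that("degenerate calibration data raises data errors", {
  expect_error(fit_allometric(tibble::tibble(area_cm2 = c(1, 2), W_g = c(1, 2))),
               class = "shellcarbon_data_error")
  # one point duplicated: rank-deficient in log-log space
  dup <- tibble::tibble(area_cm2 = rep(0.5, 4), W_g = rep(0.2, 4))
  expect_error(fit_allometric(dup), class = "shellcarbon_data_error")
  neg <- tibble::tibble(area_cm2 = c(1, 2, 3), W_g = c(1, -2, 3))
  expect_error(fit_allometric(neg), class = "shellcarbon_data_error")
})

test_that("nonlinear refinement never fits worse than its log-log start", {
  barn <- species_params(builtin_params(), "barnacle")
  for (seed in c(5, 17)) {
    samples <- generate_allometric_samples(barn, n = 80, noise_cv = 0.3,
                                           seed = seed)
    fit <- fit_allometric(samples, valve_factor = 1L,
                          weighting = "absolute")
    expect_gte(fit$r_squared, fit$r_squared_init - 1e-12)
  }
})

test_that("the fit is scale-consistent under cm^2 to mm^2 conversion", {
  barn <- species_params(builtin_params(), "barnacle")
  samples <- generate_allometric_samples(barn, n = 100, noise_cv = 0.1,
                                         seed = 8)
  fit_cm <- fit_allometric(samples, valve_factor = 1L)
  samples_mm <- samples
  samples_mm$area_cm2 <- samples$area_cm2 * 100
  fit_mm <- fit_allometric(samples_mm, valve_factor = 1L)
  expect_equal(fit_mm$params$beta, fit_cm$params$beta, tolerance = 1e-6)
  expect_equal(fit_mm$params$alpha,
               fit_cm$params$alpha / 100^fit_cm$params$beta,
               tolerance = 1e-6)
})

test_that("transfer validation computes raw-scale R squared without refitting", {
  biv <- species_params(builtin_params(), "bivalve")
  exact <- generate_allometric_samples(biv, n = 30, noise_cv = 0, seed = 4)
  expect_equal(validate_transfer(biv, exact), 1, tolerance = 1e-12)

  noisy <- generate_allometric_samples(biv, n = 100, noise_cv = 0.1, seed = 4)
  r2 <- validate_transfer(biv, noisy)
  expect_gt(r2, 0.8)
  expect_lt(r2, 1)

  # constant predictions against varying data can go negative; report as is
  flat <- tibble::tibble(area_cm2 = rep(1, 5), W_g = c(1, 2, 3, 4, 5))
  expect_lt(validate_transfer(biv, flat), 1)
  const <- tibble::tibble(area_cm2 = 1:3, W_g = rep(2, 3))
  expect_error(validate_transfer(biv, const),
               class = "shellcarbon_data_error")
})

test_that("fit objects expose tidy and glance summaries", {
  barn <- species_params(builtin_params(), "barnacle")
  fit <- fit_allometric(
    generate_allometric_samples(barn, n = 60, noise_cv = 0.1, seed = 9),
    valve_factor = 1L)
  td <- tidy(fit)
  expect_equal(td$term, c("alpha", "beta"))
  expect_true(all(c("estimate", "std.error") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$nobs, 60)
  expect_true(gl$r.squared > 0.9)
})
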