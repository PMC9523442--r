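make_test <- function(df, mode = "compression", velocity = 7,
                      geometry = sample_geometry(4, 2)) {
  deformation_test(df, mode = mode, velocity_mm_per_min = velocity,
                   geometry = geometry)
}

test_that("stress and strain arithmetic follows force/area and distance/height", {
  te <- make_test(tibble::tibble(
    time_s = c(0, 1, 2),
    displacement_mm = c(0, 0.2, 0.4),
    force_N = c(0, 0.010, 0.020)
  ))
  cu <- to_stress_strain(te, contact = "none")
  area <- pi * (2e-3)^2
  expect_equal(cu$stress_Pa[2], 0.010 / area)
  expect_equal(cu$stress_Pa[2], 795.8, tolerance = 1e-4)
  expect_equal(cu$strain[2], 0.10)

  # all-zero force maps to all-zero stress
  z <- make_test(tibble::tibble(time_s = 0:2, displacement_mm = c(0, 0.1, 0.2),
                                force_N = c(0, 0, 0)))
  expect_equal(to_stress_strain(z, contact = "none")$stress_Pa, rep(0, 3))

  # compression force is recorded negative; reported magnitudes are positive
  neg <- make_test(tibble::tibble(time_s = 0:2, displacement_mm = c(0, 0.1, 0.2),
                                  force_N = c(0, -0.01, -0.02)))
  expect_true(all(to_stress_strain(neg, contact = "none")$stress_Pa >= 0))
})

test_that("contact detection re-zeroes displacement at the 1 mN threshold", {
  te <- make_test(tibble::tibble(
    time_s = seq(0, 5, by = 1),
    displacement_mm = seq(0, 0.5, by = 0.1),
    force_N = c(0, 0.0005, 0.002, 0.01, 0.02, 0.04)
  ))
  cu <- to_stress_strain(te)
  expect_equal(nrow(cu), 4)          # samples before contact dropped
  expect_equal(cu$strain[1], 0)      # re-zeroed at contact
  expect_equal(cu$strain[2], 0.05)

  no_contact <- make_test(tibble::tibble(time_s = 0:2,
                                         displacement_mm = c(0, 0.1, 0.2),
                                         force_N = c(0, 1e-5, 2e-5)))
  expect_error(to_stress_strain(no_contact), "contact")
})

test_that("geometry validation rejects nonpositive dimensions", {
  expect_error(sample_geometry(0, 2), "positive")
  expect_error(sample_geometry(4, -1), "positive")
})

test_that("linear modulus is the OLS slope of the small-strain regime", {
  strain <- seq(0, 0.3, by = 0.01)
  exact <- new_stress_strain(
    tibble::tibble(strain = strain, stress_Pa = 3000 * strain), "compression")
  lm1 <- linear_modulus(exact, bound = 0.15)
  expect_equal(lm1$young_linear_Pa, 3000, tolerance = 1e-10)
  expect_equal(lm1$r_squared, 1)

  # noiseless van der Waals curve at a tight bound recovers 3G; the residual
  # deficit is the first-order curvature of the model over the band
  curve <- model_curve(fetal_compression_7_params(), n = 2000)
  lm2 <- linear_modulus(curve, bound = 0.01, min_points = 5)
  expect_equal(lm2$young_linear_Pa, 4441, tolerance = 0.02)

  expect_error(linear_modulus(exact, bound = 0.015), "at least")
})

test_that("linear modulus ignores uniform subsampling", {
  curve <- model_curve(fetal_compression_7_params(), n = 1000)
  sub <- new_stress_strain(tibble::as_tibble(curve)[seq(1, 1000, by = 7), ],
                           "compression")
  expect_equal(linear_modulus(sub)$young_linear_Pa,
               linear_modulus(curve)$young_linear_Pa, tolerance = 0.01)
})

test_that("maxima detection separates the global maximum from rupture peaks", {
  # strictly increasing: global max at the end, no local maxima
  inc <- model_curve(fetal_compression_7_params(), n = 100)
  mx <- detect_maxima(inc, 50)
  expect_equal(mx$global_max$strain, 0.5)
  expect_equal(nrow(mx$local_maxima), 0)

  # inserted 150 Pa drop: exactly one local maximum at the inserted location
  df <- tibble::as_tibble(inc)
  drop_idx <- 61:64
  df$stress_Pa[drop_idx] <- df$stress_Pa[drop_idx] - 150
  cu <- new_stress_strain(df, "compression")
  mx <- detect_maxima(cu, 50)
  expect_equal(nrow(mx$local_maxima), 1)
  expect_equal(mx$local_maxima$index, 60)

  # a prominence above the drop amplitude suppresses the peak
  expect_equal(nrow(detect_maxima(cu, 500)$local_maxima), 0)

  # flat zero curve
  flat <- new_stress_strain(
    tibble::tibble(strain = seq(0, 0.5, 0.1), stress_Pa = 0), "compression")
  mz <- detect_maxima(flat, 50)
  expect_equal(mz$global_max$stress_Pa, 0)
  expect_equal(nrow(mz$local_maxima), 0)
})

test_that("raising the prominence never increases the local-maximum count", {
  set.seed(4)
  base <- model_curve(fetal_compression_7_params(), n = 300)
  df <- tibble::as_tibble(base)
  df$stress_Pa <- df$stress_Pa * (1 + rnorm(300, 0, 0.05))
  cu <- new_stress_strain(df, "compression")
  counts <- vapply(c(0, 10, 25, 50, 100, 200, 400),
                   function(pr) nrow(detect_maxima(cu, pr)$local_maxima),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("fitting a noiseless model curve recovers the generating parameters", {
  truth <- vdw_params(1500, 3, 2.1)
  curve <- model_curve(truth, "compression", n = 200)
  fit <- fit_vdw(curve)
  expect_true(fit$converged)
  expect_equal(fit$params$shear_modulus_Pa, 1500, tolerance = 1e-3)
  expect_equal(fit$params$interaction, 3, tolerance = 1e-3)
  expect_equal(fit$params$limit_stretch, 2.1, tolerance = 1e-3)
  expect_equal(fit$young_vdw_Pa, young_from_shear(fit$params))

  # tension-side recovery as well (the 7 mm/min tension parameter set)
  truth_t <- vdw_params(5545 / 3, 3.2, 1.86)
  fit_t <- fit_vdw(model_curve(truth_t, "tension", n = 200))
  expect_equal(fit_t$params$shear_modulus_Pa, 5545 / 3, tolerance = 1e-3)
  expect_equal(fit_t$params$limit_stretch, 1.86, tolerance = 1e-3)
})

test_that("degenerate curves are flagged, not fitted", {
  flat <- new_stress_strain(
    tibble::tibble(strain = seq(0, 0.5, 0.01), stress_Pa = 0), "compression")
  fit <- fit_vdw(flat)
  expect_false(fit$converged)
  expect_true(is.na(fit$young_vdw_Pa))
  expect_match(fit$message, "Degenerate")
  expect_equal(nrow(tidy(fit)), 0)
})

test_that("full-range fit weights the stiffening tail above the linear slope", {
  # hyperelastic fetal-compression family: the full-range modulus matches or
  # exceeds the linear-regime slope (exact model curves can sit a fraction of
  # a percent either way from the secant bias of the linear band)
  for (v in c(1, 7)) {
    row <- dplyr::filter(fetal_vdw_table(), mode == "compression",
                         velocity == v)
    truth <- vdw_params(row$E_Pa / 3, row$a, row$lambda_m)
    fit <- fit_vdw(model_curve(truth, "compression", n = 150))
    expect_true(fit$converged)
    expect_gte(fit$young_vdw_Pa, 0.99 * fit$young_linear_Pa)
  }
})

test_that("tidy and glance expose the fitted parameters", {
  fit <- fit_vdw(model_curve(vdw_params(1500, 3, 2.1), n = 100))
  td <- tidy(fit)
  expect_setequal(td$term, c("shear_modulus_Pa", "interaction", "lambda_m",
                             "young_vdw_Pa"))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_lt(gl$rss, 1e-6)
  expect_equal(gl$young_vdw_Pa, 3 * gl$G_Pa)
})
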