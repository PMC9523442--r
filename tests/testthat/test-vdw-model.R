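test_that("deformation and conformation functions match their closed forms", {
  expect_equal(vdw_deformation(1), 0)
  expect_equal(vdw_deformation(2), 1.75)
  expect_equal(vdw_deformation(0.5), -3.5)
  expect_equal(vdw_conformation(1), 0)
  expect_equal(vdw_conformation(2), 1.0)
  expect_equal(vdw_conformation(0.5), 0.625)
  expect_error(vdw_deformation(0), "positive")
  expect_error(vdw_conformation(-1), "positive")
})

test_that("parameter validation enforces the model's domain", {
  expect_error(vdw_params(-1), "positive")
  expect_error(vdw_params(1, interaction = -0.1), "nonnegative")
  expect_error(vdw_params(1, limit_stretch = 1), "> 1")
  expect_error(vdw_params(1, poisson_ratio = 0.6), "0, 0.5")
})

test_that("nominal stress reproduces direct evaluations of the equation of state", {
  # vanishing interaction, huge limit stretch: f(2) = 1.75 / (1 - eta)
  p0 <- vdw_params(1, 0, 1000)
  eta <- sqrt(1 / vdw_conformation(1000))
  expect_equal(vdw_stress(2, p0), 1.75 / (1 - eta), tolerance = 1e-12)
  expect_equal(vdw_stress(2, p0), 1.7525, tolerance = 1e-4)

  # published fetal-compression parameters at full compression
  p <- fetal_compression_7_params()
  # independent evaluation: G * D * (1/(1-eta) - a*sqrt(phi)) assembled by hand
  D <- 0.5 - 0.5^-2
  phi <- 0.5 * (0.25 + 4 - 3)
  phi_m <- 0.5 * (2.1^2 + 2 / 2.1 - 3)
  by_hand <- (4441 / 3) * D * (1 / (1 - sqrt(phi / phi_m)) - 3 * sqrt(phi))
  expect_equal(vdw_stress(0.5, p), by_hand, tolerance = 1e-12)
  expect_equal(vdw_stress(0.5, p), -6.72e3, tolerance = 1e-3)

  # undeformed state carries no stress for any parameters
  expect_equal(vdw_stress(1, p), 0)
  expect_equal(vdw_stress(1, p0), 0)
})

test_that("evaluation beyond network extensibility errors instead of clamping", {
  p <- vdw_params(1000, 2, 1.5)
  expect_error(vdw_stress(1.5, p), class = "lungmech_extensibility_error")
  expect_error(vdw_stress(1.6, p), class = "lungmech_extensibility_error")
  expect_error(vdw_strain_energy(1.7, p), class = "lungmech_extensibility_error")
  expect_silent(vdw_stress(1.49, p))
})

test_that("strain energy is the exact potential of the stress", {
  # W(1) = 0 and f(1) = 0 for arbitrary parameters
  p <- vdw_params(1480.3, 3, 2.1)
  expect_equal(vdw_strain_energy(1, p), 0)

  # central-difference dW/dlambda equals f at a fixed point
  pp <- vdw_params(1, 0, 2.1)
  h <- 1e-6
  num <- (vdw_strain_energy(1.2 + h, pp) - vdw_strain_energy(1.2 - h, pp)) / (2 * h)
  expect_equal(num, vdw_stress(1.2, pp), tolerance = 1e-6)

  # and against an independent quadrature of f from 1 to 1.3
  quad <- stats::integrate(function(l) vdw_stress(l, p), 1, 1.3,
                           rel.tol = 1e-10)$value
  expect_equal(vdw_strain_energy(1.3, p), quad, tolerance = 1e-8)

  # property: over randomized valid parameters and stretches with eta <= 0.95
  set.seed(11)
  for (k in 1:50) {
    pr <- vdw_params(10^runif(1, 1, 4), runif(1, 0, 6), runif(1, 1.5, 3))
    lam <- runif(1, 0.55, pr$limit_stretch - 0.05)
    if (vdw_eta(lam, pr) > 0.95 || abs(lam - 1) < 0.05) next
    h <- 1e-5 * lam
    num <- (vdw_strain_energy(lam + h, pr) - vdw_strain_energy(lam - h, pr)) / (2 * h)
    expect_equal(num, vdw_stress(lam, pr), tolerance = 1e-5)
  }
})

test_that("the neo-Hookean limit is recovered as a -> 0, lambda_m -> Inf", {
  p <- vdw_params(123.4, 1e-8, 5000)
  lam <- seq(0.5, 2, by = 0.05)
  expect_equal(vdw_stress(lam, p), 123.4 * (lam - lam^-2), tolerance = 1e-3)
})

test_that("the small-strain slope equals 3G at nu = 0.5", {
  p <- vdw_params(1480.3, 3, 2.1)
  h <- 1e-6
  slope <- (vdw_stress(1 + h, p) - vdw_stress(1 - h, p)) / (2 * h)
  expect_equal(slope, 3 * p$shear_modulus_Pa, tolerance = 1e-4)
  expect_equal(young_from_shear(p), 3 * p$shear_modulus_Pa)
})

test_that("stress sign follows the deformation and diverges toward lambda_m", {
  p <- vdw_params(1000, 1, 2.1)
  lam_c <- seq(0.5, 0.99, by = 0.01)
  lam_t <- seq(1.01, 2.0, by = 0.01)
  expect_true(all(vdw_stress(lam_c, p) < 0))
  expect_true(all(vdw_stress(lam_t, p) > 0))
  # monotone unbounded approach to the extensibility limit in tension
  lam_div <- seq(1.9, 2.09, by = 0.01)
  f_div <- vdw_stress(lam_div, p)
  expect_true(all(diff(f_div) > 0))
  expect_gt(max(f_div), 100 * vdw_stress(1.5, p))
})

test_that("Young's modulus conversion covers both Poisson conventions", {
  expect_equal(young_from_shear(1000, poisson_ratio = 0.5), 3000)
  expect_equal(young_from_shear(1000, poisson_ratio = 0), 2000)
  # inverse consistency with the published fetal compression modulus
  expect_equal(young_from_shear(vdw_params(1480.33)), 4441, tolerance = 1e-4)
})
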