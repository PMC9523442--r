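#' Van der Waals network parameters
#'
#' Bundles the constitutive parameters of the van der Waals (Kilian) rubber
#' network model: the shear modulus \eqn{G}, the global interaction parameter
#' \eqn{a}, the limiting stretch \eqn{\lambda_m} (finite chain extensibility),
#' and the Poisson ratio \eqn{\nu} used to convert \eqn{G} to a Young's
#' modulus. Soft hydrated tissue is treated as incompressible, so \eqn{\nu}
#' defaults to 0.5.
#'
#' @param shear_modulus_Pa Shear modulus \eqn{G} in Pa; must be positive.
#' @param interaction Dimensionless interaction parameter \eqn{a \ge 0}.
#' @param limit_stretch Limiting stretch \eqn{\lambda_m > 1}.
#' @param poisson_ratio Poisson ratio \eqn{\nu \in [0, 0.5]}; default 0.5.
#'
#' @return An object of class `vdw_params` (a named list).
#' @examples
#' vdw_params(1480.3, interaction = 3, limit_stretch = 2.1)
#' @export
vdw_params <- function(shear_modulus_Pa,
                       interaction = 0,
                       limit_stretch = 10,
                       poisson_ratio = 0.5) {
  stopifnot(
    is.numeric(shear_modulus_Pa), length(shear_modulus_Pa) == 1L,
    is.numeric(interaction), length(interaction) == 1L,
    is.numeric(limit_stretch), length(limit_stretch) == 1L,
    is.numeric(poisson_ratio), length(poisson_ratio) == 1L
  )
  if (!is.finite(shear_modulus_Pa) || shear_modulus_Pa <= 0) {
    rlang::abort("`shear_modulus_Pa` must be a positive, finite number.")
  }
  if (!is.finite(interaction) || interaction < 0) {
    rlang::abort("`interaction` must be nonnegative.")
  }
  if (!is.finite(limit_stretch) || limit_stretch <= 1) {
    rlang::abort("`limit_stretch` must be > 1.")
  }
  if (poisson_ratio < 0 || poisson_ratio > 0.5) {
    rlang::abort("`poisson_ratio` must lie in [0, 0.5].")
  }
  structure(
    list(
      shear_modulus_Pa = shear_modulus_Pa,
      interaction = interaction,
      limit_stretch = limit_stretch,
      poisson_ratio = poisson_ratio
    ),
    class = "vdw_params"
  )
}

#' @export
print.vdw_params <- function(x, ...) {
  cat("<vdw_params>\n")
  cat(sprintf("  G        = %.6g Pa  (E = %.6g Pa at nu = %.3g)\n",
              x$shear_modulus_Pa, young_from_shear(x), x$poisson_ratio))
  cat(sprintf("  a        = %.6g\n", x$interaction))
  cat(sprintf("  lambda_m = %.6g\n", x$limit_stretch))
  invisible(x)
}

check_stretch <- function(lambda, arg = "lambda") {
  if (!is.numeric(lambda) || any(!is.finite(lambda)) || any(lambda <= 0)) {
    rlang::abort(sprintf("`%s` must be positive and finite (stretch > 0).", arg))
  }
  invisible(lambda)
}

#' Deformation function of the van der Waals network
#'
#' \eqn{D(\lambda) = \lambda - \lambda^{-2}}: zero in the undeformed state
#' (\eqn{\lambda = 1}), negative in compression, positive in tension.
#'
#' @param lambda Stretch, positive numeric vector (\eqn{\lambda = 1} is
#'   undeformed; \eqn{\lambda < 1} compression, \eqn{\lambda > 1} tension).
#' @return Numeric vector of the same length as `lambda`.
#' @examples
#' vdw_deformation(c(0.5, 1, 2))
#' @export
vdw_deformation <- function(lambda) {
  check_stretch(lambda)
  lambda - lambda^-2
}

#' Conformation function of the van der Waals network
#'
#' \eqn{\Phi(\lambda) = \tfrac12(\lambda^2 + 2/\lambda - 3)}: the first
#' strain invariant measure driving the finite-extensibility term. Zero iff
#' \eqn{\lambda = 1} and positive otherwise.
#'
#' @inheritParams vdw_deformation
#' @return Nonnegative numeric vector.
#' @examples
#' vdw_conformation(c(0.5, 1, 2))
#' @export
vdw_conformation <- function(lambda) {
  check_stretch(lambda)
  0.5 * (lambda^2 + 2 / lambda - 3)
}

#' Relative network extension eta
#'
#' \eqn{\eta(\lambda) = \sqrt{\Phi(\lambda)/\Phi(\lambda_m)}}. The model is
#' defined only for \eqn{\eta < 1}; stress diverges as \eqn{\eta \to 1}.
#'
#' @inheritParams vdw_deformation
#' @param params A [vdw_params()] object.
#' @return Numeric vector in \eqn{[0, \infty)}.
#' @export
vdw_eta <- function(lambda, params) {
  stopifnot(inherits(params, "vdw_params"))
  sqrt(vdw_conformation(lambda) / vdw_conformation(params$limit_stretch))
}

check_eta <- function(eta) {
  if (any(eta >= 1)) {
    rlang::abort(
      "Stretch beyond network extensibility: eta(lambda) >= 1 for at least one point.",
      class = "lungmech_extensibility_error"
    )
  }
  invisible(eta)
}

#' Nominal stress of the van der Waals network
#'
#' Uniaxial nominal (first Piola) stress
#' \deqn{f(\lambda) = G\,D(\lambda)\left(\frac{1}{1-\eta} - a\,\Phi^{1/2}(\lambda)\right)}
#' with \eqn{D}, \eqn{\Phi} and \eqn{\eta} as in [vdw_deformation()],
#' [vdw_conformation()] and [vdw_eta()]. \eqn{f(1) = 0} for any parameters;
#' the stress is unbounded as \eqn{\eta \uparrow 1} (strain stiffening).
#'
#' @inheritParams vdw_eta
#' @return Nominal stress in Pa, same length as `lambda`.
#' @examples
#' p <- vdw_params(1480.3, 3, 2.1)
#' vdw_stress(c(0.5, 1, 1.5), p)
#' @export
vdw_stress <- function(lambda, params) {
  stopifnot(inherits(params, "vdw_params"))
  check_stretch(lambda)
  phi <- vdw_conformation(lambda)
  eta <- sqrt(phi / vdw_conformation(params$limit_stretch))
  check_eta(eta)
  params$shear_modulus_Pa * vdw_deformation(lambda) *
    (1 / (1 - eta) - params$interaction * sqrt(phi))
}

#' Strain energy density of the van der Waals network
#'
#' \deqn{W(\lambda) = -G\left\{2\Phi_m\left[\ln(1-\eta) + \eta\right] +
#'   \tfrac{2}{3} a\,\Phi^{3/2}\right\}}
#' the potential of [vdw_stress()]: \eqn{W(1) = 0} and
#' \eqn{dW/d\lambda = f(\lambda)} exactly.
#'
#' @inheritParams vdw_eta
#' @return Strain energy density in Pa, same length as `lambda`.
#' @export
vdw_strain_energy <- function(lambda, params) {
  stopifnot(inherits(params, "vdw_params"))
  check_stretch(lambda)
  phi <- vdw_conformation(lambda)
  phi_m <- vdw_conformation(params$limit_stretch)
  eta <- sqrt(phi / phi_m)
  check_eta(eta)
  -params$shear_modulus_Pa *
    (2 * phi_m * (log1p(-eta) + eta) + (2 / 3) * params$interaction * phi^1.5)
}

#' Young's modulus from the shear modulus
#'
#' \eqn{E = 2G(1+\nu)}; for incompressible tissue (\eqn{\nu = 0.5}),
#' \eqn{E = 3G}.
#'
#' @param params A [vdw_params()] object, or a positive number interpreted as
#'   \eqn{G} in Pa.
#' @param poisson_ratio Used only when `params` is a bare number.
#' @return Young's modulus in Pa.
#' @examples
#' young_from_shear(vdw_params(1480.33))
#' young_from_shear(1000, poisson_ratio = 0)
#' @export
young_from_shear <- function(params, poisson_ratio = 0.5) {
  if (inherits(params, "vdw_params")) {
    2 * params$shear_modulus_Pa * (1 + params$poisson_ratio)
  } else {
    stopifnot(is.numeric(params), all(params > 0))
    2 * params * (1 + poisson_ratio)
  }
}

#' Evaluate a van der Waals stress-strain curve on a strain grid
#'
#' Convenience wrapper mapping engineering strain to stretch by test mode
#' (`lambda = 1 + strain` in tension, `1 - strain` in compression) and
#' returning a tidy curve. Stress is reported as a magnitude, positive in the
#' loading direction, matching processed instrument curves.
#'
#' @param strain Nonnegative engineering strains.
#' @param params A [vdw_params()] object.
#' @param mode `"tension"` or `"compression"`.
#' @return A tibble with columns `strain`, `stress_Pa`.
#' @export
vdw_curve <- function(strain, params, mode = c("tension", "compression")) {
  mode <- rlang::arg_match(mode)
  stopifnot(is.numeric(strain), all(strain >= 0), all(strain < 1))
  lambda <- strain_to_stretch(strain, mode)
  new_stress_strain(
    tibble::tibble(strain = strain, stress_Pa = abs(vdw_stress(lambda, params))),
    mode = mode
  )
}

# strain <-> stretch maps (uniaxial engineering convention)
strain_to_stretch <- function(strain, mode) {
  switch(mode, tension = 1 + strain, compression = 1 - strain)
}
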