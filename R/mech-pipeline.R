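#' Sample geometry of a punched tissue cylinder
#'
#' @param punch_diameter_mm Biopsy-punch diameter in mm (4 for fetal, 8 for
#'   adult samples).
#' @param initial_height_mm Machine-measured plate separation at contact, mm.
#' @return A `sample_geometry` list with the derived cross-section area.
#' @examples
#' sample_geometry(4, 2.0)
#' @export
sample_geometry <- function(punch_diameter_mm, initial_height_mm) {
  stopifnot(
    is.numeric(punch_diameter_mm), length(punch_diameter_mm) == 1L,
    is.numeric(initial_height_mm), length(initial_height_mm) == 1L
  )
  if (punch_diameter_mm <= 0 || initial_height_mm <= 0) {
    rlang::abort("Geometry dimensions must be positive.")
  }
  structure(
    list(
      punch_diameter_mm = punch_diameter_mm,
      initial_height_mm = initial_height_mm,
      area_m2 = pi * (punch_diameter_mm / 2 / 1000)^2
    ),
    class = "sample_geometry"
  )
}

#' Construct a deformation-test record
#'
#' A deformation test is a tibble of `(time_s, displacement_mm, force_N)`
#' samples carrying mode, velocity and geometry as attributes. Time must be
#' strictly increasing and displacement magnitude nondecreasing
#' (position-controlled constant-velocity protocol).
#'
#' @param samples Data frame with columns `time_s`, `displacement_mm`,
#'   `force_N`.
#' @param mode `"tension"` or `"compression"`.
#' @param velocity_mm_per_min Constant deformation velocity, mm/min.
#' @param geometry A [sample_geometry()] object.
#' @return A `deformation_test` tibble.
#' @export
deformation_test <- function(samples, mode = c("tension", "compression"),
                             velocity_mm_per_min, geometry) {
  mode <- rlang::arg_match(mode)
  stopifnot(inherits(geometry, "sample_geometry"),
            is.numeric(velocity_mm_per_min), velocity_mm_per_min > 0)
  required <- c("time_s", "displacement_mm", "force_N")
  missing <- setdiff(required, names(samples))
  if (length(missing)) {
    rlang::abort(sprintf("`samples` is missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  samples <- tibble::as_tibble(samples)[required]
  if (nrow(samples) == 0L) rlang::abort("`samples` must be nonempty.")
  if (any(diff(samples$time_s) <= 0)) {
    rlang::abort("`time_s` must be strictly increasing.")
  }
  if (any(diff(abs(samples$displacement_mm)) < -1e-9)) {
    rlang::abort("Displacement magnitude must be nondecreasing.")
  }
  structure(samples,
            class = c("deformation_test", class(samples)),
            mode = mode,
            velocity_mm_per_min = velocity_mm_per_min,
            geometry = geometry)
}

new_stress_strain <- function(df, mode, velocity_mm_per_min = NA_real_,
                              geometry = NULL) {
  structure(tibble::as_tibble(df),
            class = c("stress_strain", class(tibble::tibble())),
            mode = mode,
            velocity_mm_per_min = velocity_mm_per_min,
            geometry = geometry)
}

#' Convert a force-distance test to a stress-strain curve
#'
#' Engineering strain is the deformation distance relative to the sample
#' height; nominal stress is the force per undeformed cross-section area.
#' Stress is sign-normalized so magnitudes are positive in the loading
#' direction. Start of contact defaults to the first sample where the force
#' magnitude exceeds 1 mN (the contact force recorded by the instrument);
#' displacement is re-zeroed there and earlier samples are dropped. Use
#' `contact = "none"` for synthetic tests whose first sample is exactly the
#' undeformed state.
#'
#' @param test A [deformation_test()].
#' @param contact `"threshold"` (default) or `"none"`.
#' @param contact_threshold_N Contact-force threshold in N, default 1e-3.
#' @return A `stress_strain` tibble with columns `strain`, `stress_Pa`.
#' @export
to_stress_strain <- function(test, contact = c("threshold", "none"),
                             contact_threshold_N = 1e-3) {
  stopifnot(inherits(test, "deformation_test"))
  contact <- rlang::arg_match(contact)
  geometry <- attr(test, "geometry")
  df <- tibble::as_tibble(test)
  if (contact == "threshold") {
    i0 <- which(abs(df$force_N) >= contact_threshold_N)[1]
    if (is.na(i0)) {
      rlang::abort("No contact point found: force never exceeds the contact threshold.")
    }
    d0 <- df$displacement_mm[i0]
    df <- df[seq(i0, nrow(df)), ]
    df$displacement_mm <- df$displacement_mm - d0
  }
  strain <- abs(df$displacement_mm) / geometry$initial_height_mm
  if (any(strain > 0.5 + 1e-9)) {
    rlang::warn("Strain exceeds 0.5; the protocol stops at 50% strain.")
  }
  new_stress_strain(
    tibble::tibble(strain = strain, stress_Pa = abs(df$force_N) / geometry$area_m2),
    mode = attr(test, "mode"),
    velocity_mm_per_min = attr(test, "velocity_mm_per_min"),
    geometry = geometry
  )
}

default_linear_bound <- function(mode) {
  # linear elastic regime extends to ~15% strain in compression, ~10% in tension
  switch(mode, compression = 0.15, tension = 0.10, 0.15)
}

#' Young's modulus by linear regression of the small-strain regime
#'
#' Ordinary least-squares slope of nominal stress against engineering strain,
#' restricted to strains at or below `bound` (the linear elastic regime). The
#' intercept is free.
#'
#' @param curve A `stress_strain` tibble (see [to_stress_strain()]).
#' @param bound Upper strain bound of the linear regime; defaults to 0.15 for
#'   compression and 0.10 for tension.
#' @param min_points Minimum number of points required below the bound.
#' @return A one-row tibble with `young_linear_Pa`, `intercept_Pa`,
#'   `r_squared`, `n_points`, `bound`.
#' @export
linear_modulus <- function(curve, bound = NULL, min_points = 5L) {
  stopifnot(inherits(curve, "stress_strain"))
  if (is.null(bound)) bound <- default_linear_bound(attr(curve, "mode"))
  stopifnot(bound > 0, bound <= 0.5)
  sub <- dplyr::filter(tibble::as_tibble(curve), .data$strain <= bound)
  if (nrow(sub) < min_points) {
    rlang::abort(sprintf(
      "Only %d point(s) with strain <= %.3g; need at least %d for the linear fit.",
      nrow(sub), bound, min_points))
  }
  fit <- stats::lm(stress_Pa ~ strain, data = sub)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((sub$stress_Pa - mean(sub$stress_Pa))^2)
  tibble::tibble(
    young_linear_Pa = unname(stats::coef(fit)[["strain"]]),
    intercept_Pa = unname(stats::coef(fit)[["(Intercept)"]]),
    r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
    n_points = nrow(sub),
    bound = bound
  )
}

#' Detect the global stress maximum and local rupture peaks
#'
#' Local maxima are interior peaks whose stress drops by more than
#' `prominence_Pa` on both sides before a higher value is reached; they flag
#' local mechanical failure events (typically 100-200 Pa amplitude in
#' compression tests). The default prominence of 50 Pa sits below that
#' amplitude so such events are detected.
#'
#' @param curve A `stress_strain` tibble.
#' @param prominence_Pa Minimum two-sided drop for a local maximum, Pa.
#' @return A list with `global_max` (one-row tibble `strain`, `stress_Pa`)
#'   and `local_maxima` (tibble `index`, `strain`, `stress_Pa`,
#'   `prominence_Pa`, possibly empty).
#' @export
detect_maxima <- function(curve, prominence_Pa = 50) {
  stopifnot(inherits(curve, "stress_strain"), nrow(curve) > 0,
            prominence_Pa >= 0)
  s <- curve$stress_Pa
  n <- length(s)
  i_max <- which.max(s)
  global_max <- tibble::tibble(strain = curve$strain[i_max], stress_Pa = s[i_max])

  peaks <- integer(0)
  proms <- numeric(0)
  if (n >= 3) {
    for (i in 2:(n - 1)) {
      if (s[i] > s[i - 1] && s[i] >= s[i + 1]) {
        # drop on each side before a strictly higher value (or the edge)
        left <- s[seq_len(i - 1)]
        higher_l <- which(left > s[i])
        lo_l <- if (length(higher_l)) min(left[(max(higher_l) + 1):(i - 1)]) else min(left)
        right <- s[(i + 1):n]
        higher_r <- which(right > s[i])
        lo_r <- if (length(higher_r)) min(right[seq_len(min(higher_r) - 1)]) else min(right)
        prom <- s[i] - max(lo_l, lo_r)
        if (is.finite(prom) && prom > prominence_Pa) {
          peaks <- c(peaks, i)
          proms <- c(proms, prom)
        }
      }
    }
  }
  list(
    global_max = global_max,
    local_maxima = tibble::tibble(
      index = peaks,
      strain = curve$strain[peaks],
      stress_Pa = s[peaks],
      prominence_Pa = proms
    )
  )
}

# stretch > 1 with the same conformation measure as the largest observed;
# the limiting stretch must exceed this for eta < 1 on the data
equivalent_max_stretch <- function(lambda) {
  phi_max <- max(vdw_conformation(lambda))
  if (phi_max == 0) return(1)
  stats::uniroot(function(x) vdw_conformation(x) - phi_max,
                 lower = 1 + 1e-12, upper = 1e3, tol = 1e-12)$root
}

#' Fit the van der Waals model to a stress-strain curve
#'
#' Least-squares estimation of \eqn{(G, a, \lambda_m)} over the full strain
#' range, minimising the unweighted residual between the model's nominal
#' stress and the measured stress. Strain maps to stretch by test mode
#' (`1 + strain` tension, `1 - strain` compression) and the fit compares
#' signed stresses. \eqn{\lambda_m} is constrained above the largest
#' observed stretch excursion (in conformation-equivalent terms) so that
#' \eqn{\eta < 1} on all data; \eqn{a} is constrained nonnegative.
#' Optimisation uses Levenberg-Marquardt with box bounds, initialised from
#' the linear-regime modulus (\eqn{G_0 = E_{lin}/3}), with seeded random
#' restarts on failure.
#'
#' @param curve A `stress_strain` tibble.
#' @param poisson_ratio Poisson ratio used for the Young's modulus
#'   conversion; default 0.5 (not fitted).
#' @param linear_bound Strain bound for the linear-regime initialisation;
#'   mode default if `NULL`.
#' @param n_restarts Random restarts attempted if the first fit fails.
#' @param seed Seed for the restart perturbations.
#' @return An object of class `vdw_fit`: a list with `params`
#'   ([vdw_params()]), `young_vdw_Pa`, `young_linear_Pa`, `rss`, `sigma`,
#'   `converged`, `message`, `n`, and the fitted `curve`.
#' @export
fit_vdw <- function(curve, poisson_ratio = 0.5, linear_bound = NULL,
                    n_restarts = 5L, seed = 1L) {
  stopifnot(inherits(curve, "stress_strain"))
  mode <- attr(curve, "mode")
  df <- tibble::as_tibble(curve)
  lambda <- strain_to_stretch(df$strain, mode)
  sign_load <- if (mode == "compression") -1 else 1
  y <- sign_load * df$stress_Pa

  if (max(abs(y)) <= 0 || max(df$strain) <= 0) {
    return(new_vdw_fit_failure(curve, "Degenerate curve: zero stress or zero strain range."))
  }

  lam_eq <- equivalent_max_stretch(lambda)
  lower <- c(G = 1e-6, a = 0, lambda_m = lam_eq * 1.01)
  upper <- c(G = 1e6, a = 20, lambda_m = 10)

  young0 <- tryCatch(linear_modulus(curve, bound = linear_bound)$young_linear_Pa,
                     error = function(e) NA_real_)
  g0 <- if (is.finite(young0) && young0 > 0) young0 / 3 else max(abs(y)) / 2
  g0 <- min(max(g0, lower[["G"]] * 2), upper[["G"]])

  resid_fun <- function(par) {
    p <- vdw_params(par[["G"]], par[["a"]], par[["lambda_m"]], poisson_ratio)
    eta <- vdw_eta(lambda, p)
    if (any(eta >= 1)) {
      # inside bounds this cannot trigger, but guard against numeric overshoot
      return(rep(1e9, length(y)))
    }
    vdw_stress(lambda, p) - y
  }

  try_fit <- function(par0) {
    tryCatch(
      minpack.lm::nls.lm(
        par = par0, fn = resid_fun, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                             ptol = 1e-12)
      ),
      error = function(e) NULL
    )
  }

  # the deviance surface has local minima in (a, lambda_m); run a small
  # deterministic multistart and keep the best converged fit
  lam_starts <- unique(pmin(pmax(lam_eq * c(1.05, 1.2, 1.6),
                                 lower[["lambda_m"]] * 1.001), 9.99))
  starts <- tidyr::expand_grid(a = c(0.5, 2, 5, 10), lambda_m = lam_starts)
  ok <- function(f) !is.null(f) && f$info %in% 1:4
  fit <- NULL
  tss <- sum(y^2)
  for (i in seq_len(nrow(starts))) {
    cand <- try_fit(c(G = g0, a = starts$a[i], lambda_m = starts$lambda_m[i]))
    if (ok(cand) && (!ok(fit) || cand$deviance < fit$deviance)) fit <- cand
    if (ok(fit) && fit$deviance < 1e-16 * tss) break  # exact fit found
  }
  if (!ok(fit)) {
    withr::local_seed(seed)
    for (k in seq_len(n_restarts)) {
      jitter <- stats::runif(3, 0.5, 2)
      par0 <- pmin(pmax(c(G = g0, a = 2, lambda_m = lam_eq * 1.05) * jitter,
                        lower * 1.001), upper * 0.999)
      cand <- try_fit(par0)
      if (ok(cand) && (!ok(fit) || cand$deviance < fit$deviance)) fit <- cand
    }
  }
  if (!ok(fit)) {
    return(new_vdw_fit_failure(curve, "van der Waals fit did not converge after restarts."))
  }

  par <- fit$par
  params <- vdw_params(par[["G"]], par[["a"]], par[["lambda_m"]], poisson_ratio)
  structure(
    list(
      params = params,
      young_vdw_Pa = young_from_shear(params),
      young_linear_Pa = young0,
      rss = fit$deviance,
      sigma = sqrt(fit$deviance / max(length(y) - 3, 1)),
      converged = TRUE,
      message = paste("nls.lm info", fit$info),
      n = length(y),
      curve = curve
    ),
    class = "vdw_fit"
  )
}

new_vdw_fit_failure <- function(curve, msg) {
  structure(
    list(params = NULL, young_vdw_Pa = NA_real_, young_linear_Pa = NA_real_,
         rss = NA_real_, sigma = NA_real_, converged = FALSE, message = msg,
         n = nrow(curve), curve = curve),
    class = "vdw_fit"
  )
}

#' @export
print.vdw_fit <- function(x, ...) {
  cat("<vdw_fit>", if (x$converged) "converged" else "FAILED", "\n")
  if (x$converged) {
    cat(sprintf("  G = %.5g Pa, a = %.4g, lambda_m = %.4g\n",
                x$params$shear_modulus_Pa, x$params$interaction,
                x$params$limit_stretch))
    cat(sprintf("  E(vdW) = %.5g Pa, E(linear) = %.5g Pa, RSS = %.4g (n = %d)\n",
                x$young_vdw_Pa, x$young_linear_Pa, x$rss, x$n))
  } else {
    cat("  ", x$message, "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a van der Waals fit
#'
#' @param x A `vdw_fit` object.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`.
#' @export
tidy.vdw_fit <- function(x, ...) {
  if (!x$converged) {
    return(tibble::tibble(term = character(), estimate = numeric()))
  }
  tibble::tibble(
    term = c("shear_modulus_Pa", "interaction", "lambda_m", "young_vdw_Pa"),
    estimate = c(x$params$shear_modulus_Pa, x$params$interaction,
                 x$params$limit_stretch, x$young_vdw_Pa)
  )
}

#' One-row summary of a van der Waals fit
#'
#' @param x A `vdw_fit` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.vdw_fit <- function(x, ...) {
  tibble::tibble(
    young_vdw_Pa = x$young_vdw_Pa,
    young_linear_Pa = x$young_linear_Pa,
    G_Pa = if (x$converged) x$params$shear_modulus_Pa else NA_real_,
    a = if (x$converged) x$params$interaction else NA_real_,
    lambda_m = if (x$converged) x$params$limit_stretch else NA_real_,
    rss = x$rss,
    sigma = x$sigma,
    n = x$n,
    converged = x$converged
  )
}

#' Per-test modulus report
#'
#' Runs the full single-test pipeline: stress-strain conversion, linear-regime
#' modulus, van der Waals fit and peak detection, returning the flat per-test
#' record written by batch reports.
#'
#' @param test A [deformation_test()].
#' @param prominence_Pa Peak prominence threshold, Pa.
#' @param contact Contact handling passed to [to_stress_strain()].
#' @inheritParams fit_vdw
#' @return A one-row tibble.
#' @export
mech_report <- function(test, prominence_Pa = 50, contact = "threshold",
                        linear_bound = NULL, seed = 1L) {
  curve <- to_stress_strain(test, contact = contact)
  fit <- fit_vdw(curve, linear_bound = linear_bound, seed = seed)
  peaks <- detect_maxima(curve, prominence_Pa)
  dplyr::bind_cols(
    tibble::tibble(
      mode = attr(test, "mode"),
      velocity_mm_per_min = attr(test, "velocity_mm_per_min")
    ),
    glance(fit)[c("young_linear_Pa", "young_vdw_Pa", "G_Pa", "a", "lambda_m",
                  "rss", "converged")],
    tibble::tibble(
      global_max_stress_Pa = peaks$global_max$stress_Pa,
      global_max_strain = peaks$global_max$strain,
      n_local_maxima = nrow(peaks$local_maxima)
    )
  )
}
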