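#' Fractional lung volume increase during inspiration
#'
#' Tidal volume over functional residual capacity (FRC), both in ml/kg.
#' For a preterm ventilation scenario (tidal 4-6 ml/kg, FRC 21.4 ml/kg) this
#' is roughly 0.19-0.28.
#'
#' @param tidal_volume_ml_per_kg Tidal volume, ml/kg (nonnegative).
#' @param frc_ml_per_kg Functional residual capacity, ml/kg (positive).
#' @return Unrounded fraction (dimensionless).
#' @examples
#' volume_increase_fraction(4, 21.4)
#' @export
volume_increase_fraction <- function(tidal_volume_ml_per_kg, frc_ml_per_kg) {
  stopifnot(is.numeric(tidal_volume_ml_per_kg), is.numeric(frc_ml_per_kg))
  if (any(frc_ml_per_kg <= 0)) rlang::abort("`frc_ml_per_kg` must be positive.")
  if (any(tidal_volume_ml_per_kg < 0)) {
    rlang::abort("`tidal_volume_ml_per_kg` must be nonnegative.")
  }
  if (any(tidal_volume_ml_per_kg >= frc_ml_per_kg)) {
    rlang::warn("Tidal volume >= FRC; check the scenario.")
  }
  tidal_volume_ml_per_kg / frc_ml_per_kg
}

#' Linear (radius) strain for a given volume increase
#'
#' Approximating the lung as a homogeneous sphere, a fractional volume
#' increase \eqn{v} corresponds to a radius increase of
#' \eqn{(1+v)^{1/3} - 1}, the linear strain during inflation.
#'
#' @param volume_fraction Fractional volume increase (> -1).
#' @return Linear strain (dimensionless, unrounded).
#' @examples
#' radius_strain(volume_increase_fraction(4, 21.4)) # ~0.059
#' @export
radius_strain <- function(volume_fraction) {
  stopifnot(is.numeric(volume_fraction))
  if (any(volume_fraction <= -1, na.rm = TRUE)) {
    rlang::abort("`volume_fraction` must exceed -1.")
  }
  (1 + volume_fraction)^(1 / 3) - 1
}

#' Deformation velocity for a tissue sample
#'
#' Converts a linear strain reached over one inspiration into the constant
#' plate velocity applied to a punched tissue sample of given length:
#' `strain * length / inspiration_time`, reported in mm/min.
#'
#' @param linear_strain Linear strain reached during inspiration (positive).
#' @param sample_length_mm Sample length, mm (positive).
#' @param inspiration_time_s Inspiration time, s (positive).
#' @return Velocity in mm/min (unrounded).
#' @examples
#' deformation_velocity(0.0588, 2, 0.27) # ~26 mm/min
#' @export
deformation_velocity <- function(linear_strain, sample_length_mm,
                                 inspiration_time_s) {
  stopifnot(is.numeric(linear_strain), is.numeric(sample_length_mm),
            is.numeric(inspiration_time_s))
  if (any(inspiration_time_s <= 0)) {
    rlang::abort("`inspiration_time_s` must be positive.")
  }
  if (any(linear_strain <= 0, na.rm = TRUE) ||
      any(sample_length_mm <= 0)) {
    rlang::abort("Strain and sample length must be positive.")
  }
  linear_strain * sample_length_mm / inspiration_time_s * 60
}

#' Ventilation scenario to deformation-velocity table
#'
#' Composes [volume_increase_fraction()], [radius_strain()] and
#' [deformation_velocity()] over the extremes of a ventilation scenario.
#' The slow end pairs the smallest strain with the longest inspiration time
#' and the fast end the largest strain with the shortest time, bracketing
#' the physiological velocity range. If `max_linear_strain` is supplied
#' (e.g. 0.15, the elastic limit of lung expansion), an extra row gives the
#' maximal velocity: reaching that strain within the longest inspiration
#' time. All intermediate quantities are carried unrounded; the `*_pct`
#' columns are display conveniences.
#'
#' @param tidal_volume_ml_per_kg Numeric vector (range) of tidal volumes,
#'   ml/kg.
#' @param frc_ml_per_kg FRC, ml/kg.
#' @param inspiration_time_s Numeric vector (range) of inspiration times, s.
#' @param sample_length_mm Tissue sample length, mm.
#' @param max_linear_strain Optional strain cap for the maximal-velocity row.
#' @return A tibble with columns `case`, `tidal_volume_ml_per_kg`,
#'   `inspiration_time_s`, `volume_fraction`, `volume_increase_pct`,
#'   `linear_strain`, `linear_strain_pct`, `velocity_mm_per_min`.
#' @examples
#' ventilation_table(c(4, 6), 21.4, c(0.20, 0.27), 2)
#' @export
ventilation_table <- function(tidal_volume_ml_per_kg, frc_ml_per_kg,
                              inspiration_time_s, sample_length_mm = 2,
                              max_linear_strain = NULL) {
  t_lo <- min(inspiration_time_s)
  t_hi <- max(inspiration_time_s)
  rows <- tibble::tibble(
    case = c("slow", "fast"),
    tidal_volume_ml_per_kg = range(tidal_volume_ml_per_kg),
    inspiration_time_s = c(t_hi, t_lo)
  )
  rows$volume_fraction <- volume_increase_fraction(
    rows$tidal_volume_ml_per_kg, frc_ml_per_kg)
  rows$linear_strain <- radius_strain(rows$volume_fraction)
  if (!is.null(max_linear_strain)) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      case = "elastic_limit",
      tidal_volume_ml_per_kg = NA_real_,
      inspiration_time_s = t_hi,
      volume_fraction = NA_real_,
      linear_strain = max_linear_strain
    ))
  }
  rows |>
    dplyr::mutate(
      volume_increase_pct = 100 * .data$volume_fraction,
      linear_strain_pct = 100 * .data$linear_strain,
      velocity_mm_per_min = deformation_velocity(
        .data$linear_strain, sample_length_mm, .data$inspiration_time_s)
    ) |>
    dplyr::select("case", "tidal_volume_ml_per_kg", "inspiration_time_s",
                  "volume_fraction", "volume_increase_pct", "linear_strain",
                  "linear_strain_pct", "velocity_mm_per_min")
}
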