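# Default compression stiffening multipliers: ratios of the fetal-compression
# Young's moduli fitted at 1, 7 and 70 mm/min (2,646 : 4,441 : 7,617 Pa).
default_velocity_stiffening <- function() {
  c(`1` = 1, `7` = 4441 / 2646, `70` = 7617 / 2646)
}

#' Configuration for the mechanical-test generator
#'
#' Bundles the ground truth for one synthetic force-distance test. The
#' noiseless stress trace equals the van der Waals nominal stress evaluated
#' on the strain grid; under compression the shear modulus is scaled by a
#' velocity-dependent stiffening multiplier (viscoelastic rate dependence),
#' while tension is velocity-independent. Noise is multiplicative Gaussian
#' on stress by default (spread grows with stress, as in instrument curves);
#' local rupture events are inserted as step drops of 100-200 Pa amplitude.
#'
#' @param base_params A [vdw_params()] ground truth (at the slowest
#'   velocity, for compression).
#' @param mode `"tension"` or `"compression"`.
#' @param velocity_mm_per_min Deformation velocity, mm/min.
#' @param geometry A [sample_geometry()]; default fetal (4 mm punch, 2 mm
#'   height).
#' @param velocity_stiffening Named numeric vector mapping velocity to a G
#'   multiplier, applied in compression only; default the fetal-compression
#'   ratios at 1, 7 and 70 mm/min. Multipliers must be >= 1 and monotone in
#'   velocity.
#' @param noise_sd_rel Relative (multiplicative) noise standard deviation.
#' @param noise_type `"multiplicative"` or `"additive"` (additive uses
#'   `noise_sd_rel` times the maximum stress magnitude).
#' @param rupture_rate Expected rupture events per curve (Poisson), ignored
#'   when `n_ruptures` is given.
#' @param n_ruptures Exact rupture count, or `NULL`.
#' @param rupture_amplitude_Pa Length-2 range of rupture drop amplitudes.
#' @param sampling_interval_s Data-storage interval, s.
#' @param max_strain Final engineering strain of the ramp.
#' @return A `mech_gen_config` list.
#' @export
mech_gen_config <- function(base_params,
                            mode = c("compression", "tension"),
                            velocity_mm_per_min = 7,
                            geometry = sample_geometry(4, 2),
                            velocity_stiffening = NULL,
                            noise_sd_rel = 0,
                            noise_type = c("multiplicative", "additive"),
                            rupture_rate = 0,
                            n_ruptures = NULL,
                            rupture_amplitude_Pa = c(100, 200),
                            sampling_interval_s = 0.002,
                            max_strain = 0.5) {
  mode <- rlang::arg_match(mode)
  noise_type <- rlang::arg_match(noise_type)
  stopifnot(inherits(base_params, "vdw_params"),
            inherits(geometry, "sample_geometry"),
            velocity_mm_per_min > 0, noise_sd_rel >= 0,
            rupture_rate >= 0, length(rupture_amplitude_Pa) == 2,
            sampling_interval_s > 0, max_strain > 0, max_strain <= 0.5)
  if (is.null(velocity_stiffening)) {
    velocity_stiffening <- if (mode == "compression") {
      default_velocity_stiffening()
    } else {
      c(`1` = 1, `7` = 1, `70` = 1)  # tension: rate-independent
    }
  }
  vs <- velocity_stiffening[order(as.numeric(names(velocity_stiffening)))]
  if (any(vs < 1) || is.unsorted(vs)) {
    rlang::abort("Stiffening multipliers must be >= 1 and monotone in velocity.")
  }
  structure(
    list(base_params = base_params, mode = mode,
         velocity_mm_per_min = velocity_mm_per_min, geometry = geometry,
         velocity_stiffening = vs, noise_sd_rel = noise_sd_rel,
         noise_type = noise_type, rupture_rate = rupture_rate,
         n_ruptures = n_ruptures,
         rupture_amplitude_Pa = sort(rupture_amplitude_Pa),
         sampling_interval_s = sampling_interval_s, max_strain = max_strain),
    class = "mech_gen_config"
  )
}

stiffening_multiplier <- function(cfg) {
  if (cfg$mode != "compression") return(1)
  key <- as.character(cfg$velocity_mm_per_min)
  if (key %in% names(cfg$velocity_stiffening)) {
    unname(cfg$velocity_stiffening[key])
  } else {
    rlang::warn(sprintf(
      "Velocity %s has no stiffening multiplier; using 1.", key))
    1
  }
}

#' Effective generating parameters of a mechanical-test config
#'
#' The [vdw_params()] actually used on a given curve: the base parameters
#' with the shear modulus scaled by the velocity stiffening multiplier
#' (compression only).
#'
#' @param cfg A [mech_gen_config()].
#' @return A [vdw_params()] object.
#' @export
effective_params <- function(cfg) {
  stopifnot(inherits(cfg, "mech_gen_config"))
  p <- cfg$base_params
  vdw_params(p$shear_modulus_Pa * stiffening_multiplier(cfg),
             p$interaction, p$limit_stretch, p$poisson_ratio)
}

#' Generate a synthetic force-distance test
#'
#' Produces a constant-velocity ramp sampled at the configured storage
#' interval whose noiseless stress trace equals the van der Waals nominal
#' stress of the effective parameters; converts stress back to force via the
#' sample cross-section and returns a [deformation_test()]. The same seed
#' yields an identical test.
#'
#' @param cfg A [mech_gen_config()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A [deformation_test()].
#' @examples
#' cfg <- mech_gen_config(vdw_params(1500, 3, 2.1), "compression",
#'                        sampling_interval_s = 0.01)
#' test <- gen_mech_test(cfg, seed = 1)
#' @export
gen_mech_test <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "mech_gen_config"))
  if (!is.null(seed)) withr::local_seed(seed)
  params <- effective_params(cfg)
  h <- cfg$geometry$initial_height_mm
  v_mm_s <- cfg$velocity_mm_per_min / 60
  max_disp <- cfg$max_strain * h
  time_s <- seq(0, max_disp / v_mm_s, by = cfg$sampling_interval_s)
  disp <- v_mm_s * time_s
  strain <- disp / h
  lambda <- strain_to_stretch(strain, cfg$mode)
  if (any(vdw_eta(lambda, params) >= 1)) {
    rlang::abort(
      "Generating parameters reach eta >= 1 before max_strain; increase limit_stretch.")
  }
  stress <- vdw_stress(lambda, params)  # signed nominal stress
  sign_ok <- if (cfg$mode == "compression") all(stress <= 0) else all(stress >= 0)
  if (!sign_ok) {
    # a too-large interaction parameter can push the bracket term negative
    # mid-range; such parameter sets do not describe a monotone loading curve
    rlang::abort(paste(
      "Generating parameters produce stress opposing the loading direction;",
      "reduce `interaction` or increase `limit_stretch`."))
  }
  n <- length(stress)

  if (cfg$noise_sd_rel > 0) {
    if (cfg$noise_type == "multiplicative") {
      stress <- stress * (1 + stats::rnorm(n, 0, cfg$noise_sd_rel))
    } else {
      stress <- stress + stats::rnorm(n, 0, cfg$noise_sd_rel * max(abs(stress)))
    }
  }

  n_rupt <- if (!is.null(cfg$n_ruptures)) cfg$n_ruptures else {
    if (cfg$rupture_rate > 0) stats::rpois(1, cfg$rupture_rate) else 0L
  }
  if (n_rupt > 0) {
    sign_load <- if (cfg$mode == "compression") -1 else 1
    width <- max(3L, round(0.01 * n))
    eligible <- which(strain >= 0.15 & strain <= 0.45)
    eligible <- eligible[eligible + width < n]
    starts <- integer(0)
    pool <- eligible
    for (k in seq_len(n_rupt)) {
      if (!length(pool)) break
      i <- sample(pool, 1)
      starts <- c(starts, i)
      pool <- pool[abs(pool - i) > 3L * width]
    }
    amp <- stats::runif(length(starts), cfg$rupture_amplitude_Pa[1],
                        cfg$rupture_amplitude_Pa[2])
    for (k in seq_along(starts)) {
      idx <- starts[k]:(starts[k] + width - 1L)
      stress[idx] <- stress[idx] - sign_load * amp[k]
    }
  }

  force_N <- stress * cfg$geometry$area_m2
  deformation_test(
    tibble::tibble(time_s = time_s, displacement_mm = disp, force_N = force_N),
    mode = cfg$mode,
    velocity_mm_per_min = cfg$velocity_mm_per_min,
    geometry = cfg$geometry
  )
}

#' Generate a cohort of mechanical tests across velocities
#'
#' Replicate tests per velocity with per-test seeds derived from `seed`, the
#' fixture family used for velocity-dependence and group-statistics checks.
#'
#' @inheritParams mech_gen_config
#' @param velocities Velocities (mm/min) to generate.
#' @param n_per_velocity Replicates per velocity.
#' @param seed Cohort seed.
#' @param ... Passed to [mech_gen_config()].
#' @return A tibble with columns `velocity_mm_per_min`, `replicate`, `test`
#'   (list-column of [deformation_test()]).
#' @export
gen_mech_cohort <- function(base_params, mode = "compression",
                            velocities = c(1, 7, 70), n_per_velocity = 10,
                            noise_sd_rel = 0.05, seed = 1L, ...) {
  grid <- tidyr::expand_grid(velocity_mm_per_min = velocities,
                             replicate = seq_len(n_per_velocity))
  grid$test <- purrr::pmap(grid, function(velocity_mm_per_min, replicate) {
    cfg <- mech_gen_config(base_params, mode,
                           velocity_mm_per_min = velocity_mm_per_min,
                           noise_sd_rel = noise_sd_rel, ...)
    gen_mech_test(cfg, seed = seed + 1000L * match(velocity_mm_per_min,
                                                  velocities) + replicate)
  })
  grid
}

#' Configuration for the Ussing-trace generator
#'
#' Ground truth for one synthetic trace: plateau levels, the first-order
#' relaxation time, event schedule and noise. Current-clamp traces relax
#' from `start_value` to `pre_plateau`, step at the inhibitor event and
#' relax to `post_plateau` (sampled every 20 s). Voltage-clamp traces for
#' maximal-permeability assays run baseline `pre_plateau`, rise toward
#' `i_max` after the amphotericin event and decay to `post_plateau` after
#' basolateral amiloride (sampled every 5 s).
#'
#' @param clamp_mode `"current_clamp"` or `"voltage_clamp"`.
#' @param pre_plateau Baseline plateau (mV or uA/cm2 by clamp mode).
#' @param post_plateau Post-inhibitor plateau.
#' @param i_max Voltage clamp only: post-permeabilization maximum, uA/cm2.
#' @param r_te_ohm_cm2 Mean transepithelial resistance.
#' @param noise_sd Additive Gaussian noise SD on the signal.
#' @param r_noise_rel Relative noise SD on the resistance.
#' @param duration_s Trace duration.
#' @param event_times_s Named numeric vector of event times; names are event
#'   labels. `NULL` gives the default schedule for the clamp mode.
#' @param tau_s First-order relaxation time.
#' @param start_value Signal value at t = 0; defaults to half the baseline
#'   plateau.
#' @param pressure_cmH2O,pressure_side Hydrostatic-column metadata.
#' @return An `ussing_gen_config` list.
#' @export
ussing_gen_config <- function(clamp_mode = c("current_clamp", "voltage_clamp"),
                              pre_plateau = 3.6,
                              post_plateau = 1.3,
                              i_max = 7.5,
                              r_te_ohm_cm2 = 1283,
                              noise_sd = 0,
                              r_noise_rel = 0,
                              duration_s = NULL,
                              event_times_s = NULL,
                              tau_s = 60,
                              start_value = NULL,
                              pressure_cmH2O = 0,
                              pressure_side = c("none", "apical", "basolateral")) {
  clamp_mode <- rlang::arg_match(clamp_mode)
  pressure_side <- rlang::arg_match(pressure_side)
  stopifnot(r_te_ohm_cm2 > 0, noise_sd >= 0, r_noise_rel >= 0, tau_s > 0)
  if (is.null(duration_s)) {
    duration_s <- if (clamp_mode == "current_clamp") 1800 else 1500
  }
  if (is.null(event_times_s)) {
    event_times_s <- if (clamp_mode == "current_clamp") {
      c(amiloride_apical = duration_s / 2)
    } else {
      c(amphotericin_basolateral = duration_s / 5,
        amiloride_basolateral = 3 * duration_s / 5)
    }
  }
  if (length(event_times_s) &&
      (any(event_times_s <= 0) || any(event_times_s >= duration_s))) {
    rlang::abort("Event times must lie inside the trace duration.")
  }
  if (is.null(start_value)) start_value <- pre_plateau / 2
  structure(
    list(clamp_mode = clamp_mode, pre_plateau = pre_plateau,
         post_plateau = post_plateau, i_max = i_max,
         r_te_ohm_cm2 = r_te_ohm_cm2, noise_sd = noise_sd,
         r_noise_rel = r_noise_rel, duration_s = duration_s,
         event_times_s = event_times_s, tau_s = tau_s,
         start_value = start_value, pressure_cmH2O = pressure_cmH2O,
         pressure_side = pressure_side),
    class = "ussing_gen_config"
  )
}

relax_toward <- function(t, start, target, tau) {
  target + (start - target) * exp(-t / tau)
}

#' Generate a synthetic Ussing-chamber trace
#'
#' Piecewise first-order relaxation between the configured plateaus with
#' additive Gaussian noise; see [ussing_gen_config()]. The same seed yields
#' an identical trace.
#'
#' @param cfg An [ussing_gen_config()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return An [ussing_trace()].
#' @examples
#' tr <- gen_ussing_trace(ussing_gen_config(), seed = 1)
#' inhibitor_delta(tr, "amiloride_apical")
#' @export
gen_ussing_trace <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "ussing_gen_config"))
  if (!is.null(seed)) withr::local_seed(seed)
  dt <- if (cfg$clamp_mode == "current_clamp") 20 else 5
  time_s <- seq(0, cfg$duration_s, by = dt)
  ev <- cfg$event_times_s

  if (cfg$clamp_mode == "current_clamp") {
    t_ev <- if (length(ev)) min(ev) else Inf
    x <- ifelse(
      time_s < t_ev,
      relax_toward(time_s, cfg$start_value, cfg$pre_plateau, cfg$tau_s),
      NA_real_
    )
    if (is.finite(t_ev)) {
      v_at_ev <- relax_toward(t_ev, cfg$start_value, cfg$pre_plateau, cfg$tau_s)
      post <- time_s >= t_ev
      x[post] <- relax_toward(time_s[post] - t_ev, v_at_ev, cfg$post_plateau,
                              cfg$tau_s)
    }
    signal <- "v_te_mV"
  } else {
    t_amp <- if ("amphotericin_basolateral" %in% names(ev)) {
      ev[["amphotericin_basolateral"]]
    } else NA_real_
    t_ami <- if ("amiloride_basolateral" %in% names(ev)) {
      ev[["amiloride_basolateral"]]
    } else NA_real_
    x <- relax_toward(time_s, cfg$start_value, cfg$pre_plateau, cfg$tau_s)
    if (!is.na(t_amp)) {
      seg2 <- time_s >= t_amp
      x[seg2] <- relax_toward(time_s[seg2] - t_amp, cfg$pre_plateau, cfg$i_max,
                              cfg$tau_s)
      if (!is.na(t_ami)) {
        seg3 <- time_s >= t_ami
        x_ami <- relax_toward(t_ami - t_amp, cfg$pre_plateau, cfg$i_max,
                              cfg$tau_s)
        x[seg3] <- relax_toward(time_s[seg3] - t_ami, x_ami, cfg$post_plateau,
                                cfg$tau_s)
      }
    }
    signal <- "i_sc_uA_cm2"
  }

  n <- length(time_s)
  if (cfg$noise_sd > 0) x <- x + stats::rnorm(n, 0, cfg$noise_sd)
  r <- cfg$r_te_ohm_cm2 *
    (1 + if (cfg$r_noise_rel > 0) stats::rnorm(n, 0, cfg$r_noise_rel) else 0)
  samples <- tibble::tibble(time_s = time_s, r_te_ohm_cm2 = r)
  samples[[signal]] <- x
  events <- tibble::tibble(time_s = unname(ev),
                           label = names(ev) %||% character(0))
  ussing_trace(samples, events = events, clamp_mode = cfg$clamp_mode,
               pressure_cmH2O = cfg$pressure_cmH2O,
               pressure_side = cfg$pressure_side)
}

#' Generate a cohort of Ussing traces across pressure groups
#'
#' One trace per replicate per group row, seeds derived from `seed`.
#'
#' @param groups A data frame with one row per pressure group; columns
#'   `pressure_cmH2O`, `pre_plateau`, `post_plateau`, `r_te_ohm_cm2` and
#'   optionally `pressure_side`, `i_max`.
#' @param n_per_group Replicates per group.
#' @param clamp_mode Clamp mode for all traces.
#' @param noise_sd,r_noise_rel Noise levels passed to every config.
#' @param seed Cohort seed.
#' @return A tibble `pressure_cmH2O`, `replicate`, `trace` (list-column).
#' @export
gen_ussing_cohort <- function(groups, n_per_group = 30,
                              clamp_mode = "current_clamp",
                              noise_sd = 0.3, r_noise_rel = 0.02,
                              seed = 1L) {
  stopifnot(is.data.frame(groups))
  grid <- tidyr::expand_grid(row = seq_len(nrow(groups)),
                             replicate = seq_len(n_per_group))
  grid$trace <- purrr::pmap(grid, function(row, replicate) {
    g <- groups[row, ]
    cfg <- ussing_gen_config(
      clamp_mode = clamp_mode,
      pre_plateau = g$pre_plateau,
      post_plateau = g$post_plateau,
      i_max = if ("i_max" %in% names(g)) g$i_max else 7.5,
      r_te_ohm_cm2 = g$r_te_ohm_cm2,
      noise_sd = noise_sd, r_noise_rel = r_noise_rel,
      pressure_cmH2O = g$pressure_cmH2O,
      pressure_side = if ("pressure_side" %in% names(g)) g$pressure_side else "none"
    )
    gen_ussing_trace(cfg, seed = seed + 1000L * row + replicate)
  })
  tibble::tibble(pressure_cmH2O = groups$pressure_cmH2O[grid$row],
                 replicate = grid$replicate, trace = grid$trace)
}
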