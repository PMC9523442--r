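read_checked_csv <- function(path, col_types, required) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("File not found: %s", path))
  }
  # parsing issues are re-raised as errors below, so readr's warning is noise
  df <- suppressWarnings(
    readr::read_csv(path, col_types = col_types, show_col_types = FALSE))
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    rlang::abort(sprintf("%s: missing column(s): %s", path,
                         paste(missing, collapse = ", ")))
  }
  probs <- readr::problems(df)
  if (nrow(probs)) {
    rlang::abort(sprintf("%s: non-numeric or malformed cell at row %d, column %d.",
                         path, probs$row[1], probs$col[1]))
  }
  bad <- which(!stats::complete.cases(df[required]))
  if (length(bad)) {
    rlang::abort(sprintf("%s: missing value at data row %d.", path, bad[1]))
  }
  df
}

check_monotone_time <- function(df, path) {
  bad <- which(diff(df$time_s) <= 0)
  if (length(bad)) {
    rlang::abort(sprintf("%s: time_s not strictly increasing at data row %d.",
                         path, bad[1] + 1L))
  }
  df
}

#' Read a force-distance test from CSV
#'
#' Expects a header row with columns `time_s, displacement_mm, force_N`.
#' Mode, velocity and geometry are metadata the file does not carry and are
#' supplied by the caller (or a run config).
#'
#' @param path CSV file path.
#' @inheritParams deformation_test
#' @return A [deformation_test()].
#' @export
read_mech_csv <- function(path, mode, velocity_mm_per_min, geometry) {
  required <- c("time_s", "displacement_mm", "force_N")
  df <- read_checked_csv(path, readr::cols(.default = readr::col_double()),
                         required)
  check_monotone_time(df, path)
  deformation_test(df, mode = mode,
                   velocity_mm_per_min = velocity_mm_per_min,
                   geometry = geometry)
}

#' Write a force-distance test to CSV
#'
#' @param test A [deformation_test()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mech_csv <- function(test, path) {
  stopifnot(inherits(test, "deformation_test"))
  readr::write_csv(tibble::as_tibble(test), path)
  invisible(path)
}

#' Read an Ussing-chamber trace from CSV
#'
#' The trace file must hold `time_s, r_te_ohm_cm2` and either `v_te_mV`
#' (current clamp) or `i_sc_uA_cm2` (voltage clamp); the optional events
#' file holds `time_s, label`.
#'
#' @param path Trace CSV path.
#' @param events_path Optional events CSV path.
#' @inheritParams ussing_trace
#' @return An [ussing_trace()].
#' @export
read_ussing_csv <- function(path, events_path = NULL,
                            clamp_mode = c("current_clamp", "voltage_clamp"),
                            pressure_cmH2O = 0, pressure_side = "none") {
  clamp_mode <- rlang::arg_match(clamp_mode)
  signal <- if (clamp_mode == "current_clamp") "v_te_mV" else "i_sc_uA_cm2"
  df <- read_checked_csv(path, readr::cols(.default = readr::col_double()),
                         c("time_s", signal, "r_te_ohm_cm2"))
  check_monotone_time(df, path)
  events <- NULL
  if (!is.null(events_path)) {
    events <- read_checked_csv(
      events_path,
      readr::cols(time_s = readr::col_double(),
                  label = readr::col_character()),
      c("time_s", "label"))
  }
  ussing_trace(df, events = events, clamp_mode = clamp_mode,
               pressure_cmH2O = pressure_cmH2O, pressure_side = pressure_side)
}

#' Write an Ussing trace (and its events) to CSV
#'
#' @param trace An [ussing_trace()].
#' @param path Trace CSV path.
#' @param events_path Optional events CSV path.
#' @return `path`, invisibly.
#' @export
write_ussing_csv <- function(trace, path, events_path = NULL) {
  stopifnot(inherits(trace, "ussing_trace"))
  readr::write_csv(tibble::as_tibble(trace), path)
  if (!is.null(events_path)) {
    readr::write_csv(ussing_events(trace), events_path)
  }
  invisible(path)
}

#' Run the mechanical analysis pipeline from a configuration
#'
#' Executes generate-or-load, stress-strain conversion, modulus estimation
#' (linear and van der Waals) and, when several velocity groups are present,
#' the group-comparison decision tree on the fitted moduli. The config is a
#' list (or a YAML file path) with either a `simulate` block
#' (`G`, `a`, `lambda_m`, `mode`, `velocities`, `n_per_velocity`,
#' `noise_sd_rel`, optional `sampling_interval_s`) or an `inputs` list of
#' per-file records (`path`, `mode`, `velocity_mm_per_min`,
#' `punch_diameter_mm`, `initial_height_mm`), plus optional `thresholds`
#' (`linear_bound`, `prominence_Pa`) and `out_dir`.
#'
#' @param config A list or path to a YAML file.
#' @param seed Integer seed for simulation and fitting restarts.
#' @return A list with `report` (per-test tibble), `group_stats` (a
#'   `group_comparison` on `young_vdw_Pa` across velocities, or `NULL`),
#'   `config_hash` and `seed`. If `out_dir` is set, `report.csv` and
#'   `comparison.csv` are written there.
#' @export
run_mech_pipeline <- function(config, seed = 1L) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config_hash <- rlang::hash(list(config, seed))
  thresholds <- config$thresholds %||% list()
  prominence <- thresholds$prominence_Pa %||% 50
  linear_bound <- thresholds$linear_bound

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    params <- vdw_params(sim$G, sim$a %||% 0, sim$lambda_m %||% 10)
    cohort <- gen_mech_cohort(
      params,
      mode = sim$mode %||% "compression",
      velocities = unlist(sim$velocities) %||% c(1, 7, 70),
      n_per_velocity = sim$n_per_velocity %||% 10,
      noise_sd_rel = sim$noise_sd_rel %||% 0.05,
      seed = seed,
      sampling_interval_s = sim$sampling_interval_s %||% 0.002
    )
    tests <- cohort$test
    contact <- "none"
  } else if (!is.null(config$inputs) && length(config$inputs)) {
    tests <- purrr::map(config$inputs, function(rec) {
      read_mech_csv(rec$path, mode = rec$mode,
                    velocity_mm_per_min = rec$velocity_mm_per_min,
                    geometry = sample_geometry(rec$punch_diameter_mm,
                                               rec$initial_height_mm))
    })
    contact <- "threshold"
  } else {
    rlang::abort("Config must provide a `simulate` block or a nonempty `inputs` list.")
  }

  report <- purrr::imap_dfr(tests, function(test, i) {
    dplyr::bind_cols(tibble::tibble(test_id = i),
                     mech_report(test, prominence_Pa = prominence,
                                 contact = contact,
                                 linear_bound = linear_bound, seed = seed))
  })
  report$config_hash <- config_hash
  report$seed <- seed

  group_stats <- NULL
  ok <- dplyr::filter(report, .data$converged)
  if (dplyr::n_distinct(ok$velocity_mm_per_min) >= 2) {
    group_stats <- decide_and_compare(
      data.frame(group = as.character(ok$velocity_mm_per_min),
                 value = ok$young_vdw_Pa))
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(report, file.path(config$out_dir, "report.csv"))
    if (!is.null(group_stats) && nrow(tidy(group_stats))) {
      readr::write_csv(tidy(group_stats),
                       file.path(config$out_dir, "comparison.csv"))
    }
  }
  list(report = report, group_stats = group_stats,
       config_hash = config_hash, seed = seed)
}
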