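ussing_event_labels <- c("amiloride_apical", "ouabain_basolateral",
                         "amphotericin_basolateral", "amiloride_basolateral")

#' Construct an Ussing-chamber trace
#'
#' A trace is a tibble of time samples carrying inhibitor events, pressure
#' metadata and the clamp mode as attributes. Under transepithelial current
#' clamp the recorded signal is `v_te_mV` (with `r_te_ohm_cm2`), sampled
#' every 20 s; under voltage clamp it is `i_sc_uA_cm2`, sampled every 5 s.
#' Hydrostatic fluid columns are limited to 12.5 cmH2O basolaterally (cell
#' detachment above) and 30 cmH2O apically.
#'
#' @param samples Data frame with `time_s`, `r_te_ohm_cm2` and either
#'   `v_te_mV` (current clamp) or `i_sc_uA_cm2` (voltage clamp).
#' @param events Data frame with `time_s`, `label`; labels among
#'   `"amiloride_apical"`, `"ouabain_basolateral"`,
#'   `"amphotericin_basolateral"`, `"amiloride_basolateral"`. May be empty.
#' @param clamp_mode `"current_clamp"` or `"voltage_clamp"`.
#' @param pressure_cmH2O Hydrostatic column height, cmH2O (0 for controls).
#' @param pressure_side `"none"`, `"apical"` or `"basolateral"`.
#' @return An `ussing_trace` tibble.
#' @export
ussing_trace <- function(samples,
                         events = NULL,
                         clamp_mode = c("current_clamp", "voltage_clamp"),
                         pressure_cmH2O = 0,
                         pressure_side = c("none", "apical", "basolateral")) {
  clamp_mode <- rlang::arg_match(clamp_mode)
  pressure_side <- rlang::arg_match(pressure_side)
  signal <- if (clamp_mode == "current_clamp") "v_te_mV" else "i_sc_uA_cm2"
  required <- c("time_s", signal, "r_te_ohm_cm2")
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
  if (any(samples$r_te_ohm_cm2 <= 0)) {
    rlang::abort("`r_te_ohm_cm2` must be positive.")
  }
  if (is.null(events)) {
    events <- tibble::tibble(time_s = numeric(), label = character())
  }
  events <- tibble::as_tibble(events)
  bad <- setdiff(events$label, ussing_event_labels)
  if (length(bad)) {
    rlang::abort(sprintf("Unknown event label(s): %s", paste(bad, collapse = ", ")))
  }
  if (pressure_cmH2O < 0) rlang::abort("`pressure_cmH2O` must be nonnegative.")
  if (pressure_side == "basolateral" && pressure_cmH2O > 12.5) {
    rlang::abort("Basolateral fluid columns above 12.5 cmH2O detach the monolayer.")
  }
  if (pressure_side == "apical" && pressure_cmH2O > 30) {
    rlang::abort("Apical fluid columns above 30 cmH2O are outside the protocol.")
  }
  structure(samples,
            class = c("ussing_trace", class(samples)),
            events = events,
            clamp_mode = clamp_mode,
            pressure_cmH2O = pressure_cmH2O,
            pressure_side = pressure_side)
}

ussing_signal_col <- function(trace) {
  if (attr(trace, "clamp_mode") == "current_clamp") "v_te_mV" else "i_sc_uA_cm2"
}

ussing_events <- function(trace) attr(trace, "events")

#' Equivalent short-circuit current from Ohm's law
#'
#' \eqn{I_{sc} = V_{te} / R_{te}}, converted so mV over Ohm cm2 yields
#' uA/cm2.
#'
#' @param v_te_mV Transepithelial potential, mV.
#' @param r_te_ohm_cm2 Transepithelial resistance, Ohm cm2 (positive).
#' @return Short-circuit current, uA/cm2.
#' @examples
#' short_circuit_current(3.6, 1283) # ~2.8 uA/cm2
#' @export
short_circuit_current <- function(v_te_mV, r_te_ohm_cm2) {
  stopifnot(is.numeric(v_te_mV), is.numeric(r_te_ohm_cm2))
  if (any(r_te_ohm_cm2 <= 0)) rlang::abort("`r_te_ohm_cm2` must be positive.")
  v_te_mV / r_te_ohm_cm2 * 1000
}

#' Baseline transepithelial resistance of a trace
#'
#' Mean `r_te_ohm_cm2` over the samples before the first inhibitor event
#' (the whole trace if there is none).
#'
#' @param trace An [ussing_trace()].
#' @return Baseline resistance, Ohm cm2.
#' @export
baseline_r_te <- function(trace) {
  stopifnot(inherits(trace, "ussing_trace"))
  ev <- ussing_events(trace)
  r <- trace$r_te_ohm_cm2
  if (nrow(ev)) r <- r[trace$time_s < min(ev$time_s)]
  if (!length(r)) r <- trace$r_te_ohm_cm2
  mean(r)
}

#' Quality-control filter on baseline resistance
#'
#' Keeps only monolayers whose baseline transepithelial resistance strictly
#' exceeds the threshold (default 300 Ohm cm2); leakier monolayers are
#' excluded from analysis.
#'
#' @param traces A list of [ussing_trace()] objects.
#' @param threshold_ohm_cm2 Inclusion threshold, Ohm cm2 (strict).
#' @return The filtered list.
#' @export
qc_filter <- function(traces, threshold_ohm_cm2 = 300) {
  stopifnot(is.list(traces))
  purrr::keep(traces, \(tr) baseline_r_te(tr) > threshold_ohm_cm2)
}

window_slope_mean <- function(x) {
  n <- length(x)
  idx <- seq_len(n) - 1
  # closed-form OLS slope against sample index, with its standard error
  sxx <- sum((idx - mean(idx))^2)
  slope <- sum((idx - mean(idx)) * (x - mean(x))) / sxx
  resid <- x - mean(x) - slope * (idx - mean(idx))
  se <- if (n > 2) sqrt(sum(resid^2) / (n - 2) / sxx) else 0
  c(slope = slope, mean = mean(x), se = se)
}

# a window is flat when its slope is negligible relative to the level or
# statistically indistinguishable from zero
window_is_flat <- function(sm, rel_slope_tol) {
  abs(sm[["slope"]]) <= max(rel_slope_tol * abs(sm[["mean"]]), 2 * sm[["se"]])
}

#' Detect the earliest stable plateau of a signal
#'
#' Slides a window of `window_n` samples along the signal and reports the
#' earliest flat window. A window is flat when its least-squares slope (per
#' sample) is below `rel_slope_tol` times the window mean magnitude, or is
#' statistically indistinguishable from zero (within twice its standard
#' error; this keeps near-zero plateaus detectable under noise). With the
#' default 20 s sampling, six samples span two minutes.
#'
#' @param x Numeric vector, or an [ussing_trace()] (its clamp-mode signal is
#'   used).
#' @param window_n Window length in samples.
#' @param rel_slope_tol Maximum |slope| / |mean| per sample.
#' @return A list with `start_index` (NA if no plateau) and `plateau_mean`.
#' @export
detect_plateau <- function(x, window_n = 6L, rel_slope_tol = 0.01) {
  if (inherits(x, "ussing_trace")) x <- x[[ussing_signal_col(x)]]
  stopifnot(is.numeric(x), window_n >= 2L)
  n <- length(x)
  if (n < window_n) {
    rlang::abort("Signal shorter than the plateau window.")
  }
  for (i in seq_len(n - window_n + 1L)) {
    sm <- window_slope_mean(x[i:(i + window_n - 1L)])
    if (window_is_flat(sm, rel_slope_tol)) {
      return(list(start_index = i, plateau_mean = sm[["mean"]]))
    }
  }
  list(start_index = NA_integer_, plateau_mean = NA_real_)
}

# plateau reached before an event: the latest stable window in the segment
# (backward scan, so a noisy final window does not discard the trace)
plateau_before <- function(x, window_n, rel_slope_tol) {
  n <- length(x)
  if (n < window_n) return(list(start_index = NA_integer_, plateau_mean = NA_real_))
  for (i in (n - window_n + 1L):1L) {
    sm <- window_slope_mean(x[i:(i + window_n - 1L)])
    if (window_is_flat(sm, rel_slope_tol)) {
      return(list(start_index = i, plateau_mean = sm[["mean"]]))
    }
  }
  list(start_index = NA_integer_, plateau_mean = NA_real_)
}

event_time <- function(trace, label) {
  ev <- ussing_events(trace)
  t <- ev$time_s[ev$label == label]
  if (length(t)) t[1] else NA_real_
}

#' Inhibitor-sensitive signal change
#'
#' Computes the drop in the recorded signal caused by an inhibitor: the
#' plateau reached just before the event minus the plateau reached after it.
#' Both plateaus are the latest flat window of their segment, so the
#' post-event value is taken after the response has fully relaxed.
#' For current-clamp voltage traces with apical amiloride this is the
#' amiloride-sensitive potential (delta V_amil); with basolateral ouabain,
#' delta V_ouab; for clamped current, the inhibitor-sensitive delta I_sc.
#' Deltas use plateau means, not single samples, for noise robustness.
#'
#' @param trace An [ussing_trace()].
#' @param event_label One of the inhibitor event labels.
#' @inheritParams detect_plateau
#' @return A one-row tibble `pre_plateau`, `post_plateau`, `delta`, `flag`
#'   (`NA` when clean; otherwise the reason the computation is unusable).
#' @examples
#' # see gen_ussing_trace() for fixture construction
#' @export
inhibitor_delta <- function(trace, event_label = "amiloride_apical",
                            window_n = 6L, rel_slope_tol = 0.01) {
  stopifnot(inherits(trace, "ussing_trace"))
  event_label <- rlang::arg_match(event_label, ussing_event_labels)
  out <- tibble::tibble(pre_plateau = NA_real_, post_plateau = NA_real_,
                        delta = NA_real_, flag = NA_character_)
  t_ev <- event_time(trace, event_label)
  if (is.na(t_ev)) {
    out$flag <- paste0("missing event: ", event_label)
    return(out)
  }
  x <- trace[[ussing_signal_col(trace)]]
  pre <- x[trace$time_s < t_ev]
  post <- x[trace$time_s >= t_ev]
  if (length(pre) < window_n || length(post) < window_n) {
    out$flag <- "too few samples around event"
    return(out)
  }
  p_pre <- plateau_before(pre, window_n, rel_slope_tol)
  p_post <- plateau_before(post, window_n, rel_slope_tol)
  if (is.na(p_pre$start_index)) {
    out$flag <- "no pre-event plateau"
    return(out)
  }
  if (is.na(p_post$start_index)) {
    out$flag <- "no post-event plateau"
    return(out)
  }
  out$pre_plateau <- p_pre$plateau_mean
  out$post_plateau <- p_post$plateau_mean
  out$delta <- p_pre$plateau_mean - p_post$plateau_mean
  out
}

#' Maximal amiloride-sensitive apical current
#'
#' After basolateral permeabilization with amphotericin B, the short-circuit
#' current rises to a maximum set by apical Na+ entry alone; basolateral
#' amiloride then blocks the epithelial sodium channel. The maximal
#' amiloride-sensitive permeability is the post-permeabilization maximum
#' minus the post-amiloride plateau.
#'
#' @param trace A voltage-clamp [ussing_trace()] with
#'   `amphotericin_basolateral` and `amiloride_basolateral` events.
#' @inheritParams detect_plateau
#' @return A one-row tibble `i_max`, `post_plateau`, `amil_max_uA_cm2`,
#'   `flag`.
#' @export
amil_max <- function(trace, window_n = 6L, rel_slope_tol = 0.01) {
  stopifnot(inherits(trace, "ussing_trace"))
  out <- tibble::tibble(i_max = NA_real_, post_plateau = NA_real_,
                        amil_max_uA_cm2 = NA_real_, flag = NA_character_)
  if (attr(trace, "clamp_mode") != "voltage_clamp") {
    out$flag <- "amil_max requires a voltage-clamp trace"
    return(out)
  }
  t_amp <- event_time(trace, "amphotericin_basolateral")
  t_ami <- event_time(trace, "amiloride_basolateral")
  if (is.na(t_amp) || is.na(t_ami)) {
    out$flag <- "missing amphotericin or basolateral-amiloride event"
    return(out)
  }
  x <- trace$i_sc_uA_cm2
  rise <- x[trace$time_s >= t_amp & trace$time_s < t_ami]
  post <- x[trace$time_s >= t_ami]
  if (!length(rise) || length(post) < window_n) {
    out$flag <- "too few samples around events"
    return(out)
  }
  p_post <- plateau_before(post, window_n, rel_slope_tol)
  if (is.na(p_post$start_index)) {
    out$flag <- "no post-amiloride plateau"
    return(out)
  }
  out$i_max <- max(rise)
  out$post_plateau <- p_post$plateau_mean
  out$amil_max_uA_cm2 <- out$i_max - out$post_plateau
  out
}

#' Transport summary of one Ussing trace
#'
#' Runs the per-trace quantification: baseline plateau, inhibitor-sensitive
#' components and QC. For current-clamp traces the summary holds `v_base_mV`
#' (pre-amiloride plateau), `v_amil_mV` (post-amiloride plateau, the
#' amiloride-insensitive component), `delta_amil_mV` (their difference) and,
#' when a ouabain event is present, `delta_ouab_mV`; the equivalent
#' short-circuit current of the baseline is derived from Ohm's law. For
#' voltage-clamp traces it holds `amil_max_uA_cm2`.
#'
#' @param trace An [ussing_trace()].
#' @inheritParams detect_plateau
#' @param qc_threshold_ohm_cm2 Baseline-resistance inclusion threshold.
#' @return A one-row tibble; `qc_pass` reports the resistance gate and
#'   `flag` any failed computation.
#' @export
summarize_ussing_trace <- function(trace, window_n = 6L, rel_slope_tol = 0.01,
                                   qc_threshold_ohm_cm2 = 300) {
  stopifnot(inherits(trace, "ussing_trace"))
  base_r <- baseline_r_te(trace)
  out <- tibble::tibble(
    clamp_mode = attr(trace, "clamp_mode"),
    pressure_cmH2O = attr(trace, "pressure_cmH2O"),
    pressure_side = attr(trace, "pressure_side"),
    r_te_baseline_ohm_cm2 = base_r,
    qc_pass = base_r > qc_threshold_ohm_cm2,
    v_base_mV = NA_real_, v_amil_mV = NA_real_, delta_amil_mV = NA_real_,
    delta_ouab_mV = NA_real_, i_sc_base_uA_cm2 = NA_real_,
    r_te_at_plateau = NA_real_, amil_max_uA_cm2 = NA_real_,
    flag = NA_character_
  )
  if (attr(trace, "clamp_mode") == "current_clamp") {
    da <- inhibitor_delta(trace, "amiloride_apical", window_n, rel_slope_tol)
    out$v_base_mV <- da$pre_plateau
    out$v_amil_mV <- da$post_plateau
    out$delta_amil_mV <- da$delta
    out$flag <- da$flag
    t_ev <- event_time(trace, "amiloride_apical")
    if (!is.na(t_ev) && !is.na(da$pre_plateau)) {
      pre_r <- trace$r_te_ohm_cm2[trace$time_s < t_ev]
      out$r_te_at_plateau <- mean(utils::tail(pre_r, window_n))
      out$i_sc_base_uA_cm2 <- short_circuit_current(da$pre_plateau,
                                                    out$r_te_at_plateau)
    }
    if (!is.na(event_time(trace, "ouabain_basolateral"))) {
      do <- inhibitor_delta(trace, "ouabain_basolateral", window_n, rel_slope_tol)
      out$delta_ouab_mV <- do$delta
      if (is.na(out$flag)) out$flag <- do$flag
    }
  } else {
    am <- amil_max(trace, window_n, rel_slope_tol)
    out$amil_max_uA_cm2 <- am$amil_max_uA_cm2
    out$flag <- am$flag
  }
  out
}

#' Group-level aggregate of trace summaries
#'
#' Mean, standard error and n per pressure group for each quantified
#' component, over QC-passing, unflagged traces.
#'
#' @param summaries A tibble of [summarize_ussing_trace()] rows.
#' @return A tibble with `pressure_cmH2O`, `pressure_side`, `metric`,
#'   `mean`, `sem`, `n`.
#' @export
ussing_group_summary <- function(summaries) {
  metrics <- c("v_base_mV", "v_amil_mV", "delta_amil_mV", "delta_ouab_mV",
               "i_sc_base_uA_cm2", "amil_max_uA_cm2", "r_te_at_plateau",
               "r_te_baseline_ohm_cm2")
  summaries |>
    dplyr::filter(.data$qc_pass, is.na(.data$flag)) |>
    tidyr::pivot_longer(dplyr::any_of(metrics), names_to = "metric") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$pressure_cmH2O, .data$pressure_side, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sem = stats::sd(.data$value) / sqrt(dplyr::n()),
      n = dplyr::n(),
      .groups = "drop"
    )
}
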