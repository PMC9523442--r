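make_cc_trace <- function(v, r = 1283, dt = 20, events = NULL, ...) {
  n <- length(v)
  ussing_trace(
    tibble::tibble(time_s = seq(0, by = dt, length.out = n),
                   v_te_mV = v, r_te_ohm_cm2 = rep_len(r, n)),
    events = events, clamp_mode = "current_clamp", ...)
}

test_that("short-circuit current follows Ohm's law in chamber units", {
  expect_equal(short_circuit_current(3.6, 1283), 2.806, tolerance = 1e-3)
  expect_equal(short_circuit_current(0, 500), 0)
  # linear in V_te, inversely proportional to R_te
  v <- seq(-5, 5, by = 0.5)
  expect_equal(short_circuit_current(2 * v, 1000),
               2 * short_circuit_current(v, 1000))
  expect_equal(short_circuit_current(3.6, 2 * 1283),
               short_circuit_current(3.6, 1283) / 2)
  expect_error(short_circuit_current(3.6, 0), "positive")
})

test_that("the resistance gate is strict at the 300 Ohm cm2 threshold", {
  at <- make_cc_trace(rep(3, 10), r = 300)
  above <- make_cc_trace(rep(3, 10), r = 301)
  below <- make_cc_trace(rep(3, 10), r = 120)
  expect_length(qc_filter(list(at, above, below)), 1)
  expect_equal(baseline_r_te(qc_filter(list(at, above, below))[[1]]), 301)
  expect_length(qc_filter(list()), 0)
})

test_that("plateau detection finds the earliest stable window", {
  # constant series: plateau from the first sample
  p <- detect_plateau(rep(3.6, 20), window_n = 6)
  expect_equal(p$start_index, 1)
  expect_equal(p$plateau_mean, 3.6)

  # ramp then constant: the start falls within the constant segment
  x <- c(seq(0.5, 3.4, length.out = 10), rep(3.6, 20))
  p <- detect_plateau(x, window_n = 6)
  expect_gte(p$start_index, 10)
  expect_equal(p$plateau_mean, 3.6, tolerance = 0.02)

  # strictly increasing: no plateau
  p <- detect_plateau(seq(1, 30), window_n = 6)
  expect_true(is.na(p$start_index))

  expect_error(detect_plateau(1:3, window_n = 6), "shorter")
})

test_that("inhibitor deltas use plateau means and flag missing pieces", {
  ev <- tibble::tibble(time_s = 400, label = "amiloride_apical")
  v <- c(rep(3.6, 20), rep(1.3, 20))
  tr <- make_cc_trace(v, events = ev)
  d <- inhibitor_delta(tr, "amiloride_apical")
  expect_equal(d$pre_plateau, 3.6)
  expect_equal(d$post_plateau, 1.3)
  expect_equal(d$delta, 2.3)
  expect_true(is.na(d$flag))

  # pre == post gives zero delta
  d0 <- inhibitor_delta(make_cc_trace(rep(2, 40), events = ev),
                        "amiloride_apical")
  expect_equal(d0$delta, 0)

  # missing event
  dm <- inhibitor_delta(make_cc_trace(rep(2, 40)), "amiloride_apical")
  expect_match(dm$flag, "missing event")
  expect_true(is.na(dm$delta))

  # no post-event plateau on a steadily drifting signal
  drift <- c(rep(3.6, 20), seq(3.5, 1, length.out = 20))
  dd <- inhibitor_delta(make_cc_trace(drift, events = ev), "amiloride_apical")
  expect_match(dd$flag, "no post-event plateau")
})

test_that("noisy inhibitor deltas recover the configured change", {
  set.seed(9)
  sd <- 0.05
  deltas <- vapply(1:20, function(k) {
    cfg <- ussing_gen_config(pre_plateau = 3.6, post_plateau = 1.3,
                             noise_sd = sd, tau_s = 40)
    inhibitor_delta(gen_ussing_trace(cfg, seed = 100 + k),
                    "amiloride_apical")$delta
  }, numeric(1))
  # plateau means average ~6 samples; allow 3 sigma/sqrt(n) plus the small
  # relaxation-tail bias of the earliest-window rule
  expect_equal(mean(deltas), 2.3, tolerance = 3 * sd / sqrt(6 * 20) / 2.3 + 0.02)
})

test_that("amil_max is the permeabilized maximum minus the blocked plateau", {
  cfg <- ussing_gen_config("voltage_clamp", pre_plateau = 1, post_plateau = 0.3,
                           i_max = 7.5, tau_s = 30)
  am <- amil_max(gen_ussing_trace(cfg, seed = 1))
  expect_true(is.na(am$flag))
  expect_equal(am$amil_max_uA_cm2, 7.2, tolerance = 0.02)

  # flat-zero trace with events present yields zero
  n <- 101
  tr0 <- ussing_trace(
    tibble::tibble(time_s = seq(0, 500, by = 5), i_sc_uA_cm2 = 0,
                   r_te_ohm_cm2 = 1000),
    events = tibble::tibble(time_s = c(100, 300),
                            label = c("amphotericin_basolateral",
                                      "amiloride_basolateral")),
    clamp_mode = "voltage_clamp")
  am0 <- amil_max(tr0)
  expect_equal(am0$amil_max_uA_cm2, 0)

  # missing events flagged
  trm <- gen_ussing_trace(ussing_gen_config("voltage_clamp",
                                            event_times_s = c(amphotericin_basolateral = 300)))
  expect_match(amil_max(trm)$flag, "missing")

  # current-clamp traces are rejected
  cc <- gen_ussing_trace(ussing_gen_config(), seed = 2)
  expect_match(amil_max(cc)$flag, "voltage-clamp")
})

test_that("the transport summary decomposes additively and converts to current", {
  tr <- gen_ussing_trace(ussing_gen_config(pre_plateau = 3.6,
                                           post_plateau = 1.3,
                                           r_te_ohm_cm2 = 1283,
                                           tau_s = 30), seed = 5)
  s <- summarize_ussing_trace(tr)
  expect_equal(s$v_base_mV - s$v_amil_mV - s$delta_amil_mV, 0)
  expect_equal(s$v_base_mV, 3.6, tolerance = 1e-3)
  expect_equal(s$i_sc_base_uA_cm2,
               short_circuit_current(s$v_base_mV, s$r_te_at_plateau))
  expect_true(s$qc_pass)
})

test_that("group aggregation reports mean, SEM and n per pressure", {
  groups <- tibble::tibble(
    pressure_cmH2O = c(0, 12.5),
    pre_plateau = c(3.6, 0.9),
    post_plateau = c(1.3, 0.21),
    r_te_ohm_cm2 = c(1283, 377),
    pressure_side = c("none", "basolateral")
  )
  cohort <- gen_ussing_cohort(groups, n_per_group = 12, noise_sd = 0.1,
                              seed = 3)
  summaries <- purrr::map_dfr(cohort$trace, summarize_ussing_trace)
  agg <- ussing_group_summary(summaries)
  da <- dplyr::filter(agg, metric == "delta_amil_mV")
  expect_equal(nrow(da), 2)
  truth <- c(3.6 - 1.3, 0.9 - 0.21)
  got <- da$mean[order(da$pressure_cmH2O)]
  expect_equal(got, truth, tolerance = 0.1)
  expect_true(all(da$n == 12))
})

test_that("trace construction enforces protocol pressure limits", {
  s <- tibble::tibble(time_s = c(0, 20), v_te_mV = c(1, 1),
                      r_te_ohm_cm2 = c(500, 500))
  expect_error(ussing_trace(s, clamp_mode = "current_clamp",
                            pressure_cmH2O = 15,
                            pressure_side = "basolateral"), "12.5")
  expect_error(ussing_trace(s, clamp_mode = "current_clamp",
                            pressure_cmH2O = 35, pressure_side = "apical"),
               "30")
  expect_silent(ussing_trace(s, clamp_mode = "current_clamp",
                             pressure_cmH2O = 12.5,
                             pressure_side = "basolateral"))
})
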