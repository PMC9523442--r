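# Published mean van der Waals parameters for fetal lung tissue, used as
# generating ground truth for synthetic fixtures (E in Pa; G = E/3 at nu = 0.5).
fetal_vdw_table <- function() {
  tibble::tibble(
    mode = rep(c("compression", "tension"), each = 3),
    velocity = rep(c(1, 7, 70), 2),
    E_Pa = c(2646, 4441, 7617, 6607, 5545, 8221),
    lambda_m = c(2.1, 2.10, 2.12, 1.9, 1.86, 1.81),
    a = c(1.9, 3.0, 2.7, 5.8, 3.2, 4.3)
  )
}

fetal_compression_7_params <- function() {
  vdw_params(4441 / 3, interaction = 3.0, limit_stretch = 2.10)
}

# fast-sampling config for fit tests (coarser grid than the 2 ms instrument
# interval keeps fixture curves at a few hundred points)
quick_mech_cfg <- function(params, mode = "compression", velocity = 7, ...) {
  mech_gen_config(params, mode, velocity_mm_per_min = velocity,
                  sampling_interval_s = 0.05, ...)
}

# stress-strain curve evaluated directly from the model (no generator)
model_curve <- function(params, mode = "compression", n = 200,
                        max_strain = 0.5) {
  vdw_curve(seq(0, max_strain, length.out = n), params, mode)
}
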