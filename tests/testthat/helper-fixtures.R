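# Shared fixtures: small, fast configurations used across test files.
# Speed-critical simulations use a short hold with a correspondingly fast
# characteristic time so every hold still reaches equilibrium.

fix_geom <- function(thickness = 200e-6) sample_geometry(thickness = thickness)

# Fast material: tau_g = a^2/(H+A k) = 25 s, so a 300 s hold is ~12 tau.
fix_params_fast <- function() cle_parameters(H_plus_A = 100e3, H_minus_A = 30e3,
                                             k = 1e-13)

fix_program_fast <- function(strains = 0.05) {
  loading_program(strains, ramp_duration = 5, hold_duration = 300)
}

# Printed group-mean truths used for recovery tests (treated / control arms).
fix_truth_ra <- function() cle_parameters(104e3, 30e3, 0.96e-14)
fix_truth_ctrl <- function() cle_parameters(160e3, 30e3, 0.73e-14)

# Single-step trace config around a given truth (noise optional).
fix_single_step_config <- function(params, ramp = 10, hold = 1500,
                                   noise = 0, group = "RA") {
  cfgH <- list(); cfgk <- list(); cfgHm <- list()
  cfgH[[group]] <- params$H_plus_A
  cfgk[[group]] <- params$k
  cfgHm[[group]] <- params$H_minus_A
  trace_config(
    H_plus_A = cfgH, k = cfgk, H_minus_A = cfgHm,
    between_sample_cv = stats::setNames(
      list(c(H = 0.5, k = 0.4)), group),
    program = loading_program(0.05, ramp_duration = ramp, hold_duration = hold),
    load_noise_sd = noise
  )
}

# Small cohort table built by hand for identity checks.
fix_mini_cohort <- function() {
  data.frame(
    animal_id = rep(c("C1", "C2", "R1", "R2"), each = 4L),
    eye = rep(c("OD", "OS"), times = 8L),
    treatment = rep(c("Ctrl", "Ctrl", "RA", "RA"), each = 4L),
    timepoint = rep(rep(c("t0", "t2wk"), each = 2L), times = 4L),
    age_days = 28,
    outcome = "VCD",
    value = c(800, 802, 810, 812,   820, 818, 830, 832,
              805, 807, 840, 842,   815, 813, 850, 848),
    excluded = FALSE, reason = NA_character_
  )
}

rel_rms <- function(x, ref) sqrt(mean((x - ref)^2)) / sqrt(mean(ref^2))
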