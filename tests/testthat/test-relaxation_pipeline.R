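# Trace -> estimate pipeline: tare/thickness detection, segmentation,
# per-step fitting, and the identifiability / robustness properties.

test_that("tare detection recovers the generator's post-tare thickness", {
  cfg <- fix_single_step_config(fix_params_fast(), ramp = 5, hold = 300)
  ds <- gen_relaxation_dataset(cfg, n_per_group = c(RA = 1), seed = 11,
                               sample_variation = FALSE)
  tare <- detect_tare_and_thickness(ds$traces[[1L]])
  expect_equal(tare$thickness, 200e-6, tolerance = 1e-6 / 200e-6)
  expect_false(tare$drift_flagged)
})

test_that("tare detection errors on a zero-load trace and flags drift", {
  flat <- relaxation_trace(0:100, rep(0, 101), rep(0, 101), initial_gap = 2e-4)
  expect_error(detect_tare_and_thickness(flat), "tare never reached")

  # drifting load during the tare equilibrium window: flagged, thickness kept
  t <- 0:200
  disp <- c(seq(0, 10e-6, length.out = 11L), rep(10e-6, 140L),
            seq(10e-6, 20e-6, length.out = 50L))
  load <- c(seq(0, 550e-6, length.out = 11L),
            550e-6 + 2e-6 * seq_len(140L), rep(9e-4, 50L))
  tr <- relaxation_trace(t, disp, load, initial_gap = 210e-6)
  tare <- detect_tare_and_thickness(tr)
  expect_true(tare$drift_flagged)
  expect_equal(tare$thickness, 200e-6, tolerance = 0.01)
})

test_that("segmentation finds the programmed steps with increasing equilibria", {
  cfg <- trace_config(program = loading_program(c(0.05, 0.10, 0.15),
                                                ramp_duration = 5,
                                                hold_duration = 250),
                      H_plus_A = list(Ctrl = rep(100e3, 3)),
                      k = list(Ctrl = rep(1e-13, 3)),
                      H_minus_A = list(Ctrl = rep(30e3, 3)),
                      between_sample_cv = list(Ctrl = c(H = 0.5, k = 0.4)))
  ds <- gen_relaxation_dataset(cfg, n_per_group = c(Ctrl = 1), seed = 3,
                               sample_variation = FALSE)
  segs <- segment_steps(ds$traces[[1L]], cfg$program)
  expect_equal(nrow(segs), 3L)
  expect_equal(segs$applied_strain, c(0.05, 0.10, 0.15), tolerance = 0.01)
  expect_false(any(segs$strain_flagged))
  # fixed H-A: equilibrium load proportional to cumulative strain
  expect_true(all(diff(segs$equilibrium_load) > 0))

  # a single-step trace cannot satisfy a 3-step program
  cfg1 <- fix_single_step_config(fix_params_fast(), ramp = 5, hold = 300)
  ds1 <- gen_relaxation_dataset(cfg1, n_per_group = c(RA = 1), seed = 4,
                                sample_variation = FALSE)
  expect_error(segment_steps(ds1$traces[[1L]], cfg$program), "detected 1 ramp")
})

test_that("noise-free single-step fits recover printed group means within 0.5%", {
  for (truth in list(fix_truth_ra(), fix_truth_ctrl())) {
    cfg <- fix_single_step_config(truth)
    ds <- gen_relaxation_dataset(cfg, n_per_group = c(RA = 1), seed = 1,
                                 sample_variation = FALSE)
    fit <- fit_sample(ds$traces[[1L]], program = cfg$program)
    expect_true(fit$converged[1L])
    expect_equal(fit$H_plus_A_Pa[1L], truth$H_plus_A, tolerance = 0.005)
    expect_equal(fit$k_m4_per_Ns[1L], truth$k, tolerance = 0.005)
    expect_equal(fit$H_minus_A_Pa[1L], truth$H_minus_A, tolerance = 0.005)
  }
})

test_that("equilibrium consistency holds exactly by construction", {
  cfg <- fix_single_step_config(fix_params_fast(), ramp = 5, hold = 300)
  ds <- gen_relaxation_dataset(cfg, n_per_group = c(RA = 1), seed = 5,
                               sample_variation = FALSE)
  trace <- ds$traces[[1L]]
  tare <- detect_tare_and_thickness(trace)
  geom <- sample_geometry(thickness = tare$thickness)
  segs <- segment_steps(trace, cfg$program, thickness = tare$thickness,
                        t_start = tare$t_tare_end)
  est <- fit_step(segs[1L, ], trace, geom,
                  prev_equilibrium_load = cfg$program$tare_load)
  expect_equal(est$H_minus_A_hat * est$d_strain * geom$area,
               segs$equilibrium_load[1L] - cfg$program$tare_load,
               tolerance = 1e-12)
})

test_that("fitting is stable to 2x resampling and degenerate transients fail cleanly", {
  truth <- fix_params_fast()
  for (fs in c(1, 2)) {
    cfg <- fix_single_step_config(truth, ramp = 5, hold = 300)
    cfg$sampling_rate <- fs
    ds <- gen_relaxation_dataset(cfg, n_per_group = c(RA = 1), seed = 6,
                                 sample_variation = FALSE)
    fit <- fit_sample(ds$traces[[1L]], program = cfg$program)
    expect_equal(fit$H_plus_A_Pa[1L], truth$H_plus_A, tolerance = 1e-3)
    expect_equal(fit$k_m4_per_Ns[1L], truth$k, tolerance = 1e-3)
  }

  # H+A << H-A: peak/equilibrium below 1.02 -> "insufficient transient"
  weak <- cle_parameters(100, 30e3, 1e-13)
  cfgw <- fix_single_step_config(weak, ramp = 5, hold = 300)
  dsw <- gen_relaxation_dataset(cfgw, n_per_group = c(RA = 1), seed = 7,
                                sample_variation = FALSE)
  fitw <- fit_sample(dsw$traces[[1L]], program = cfgw$program)
  expect_false(fitw$converged[1L])
  expect_match(fitw$reason[1L], "insufficient transient")
})

test_that("a corrupted step yields a failure record without aborting the others", {
  cfg <- trace_config(program = loading_program(c(0.05, 0.10, 0.15),
                                                ramp_duration = 5,
                                                hold_duration = 250),
                      H_plus_A = list(Ctrl = rep(100e3, 3)),
                      k = list(Ctrl = rep(1e-13, 3)),
                      H_minus_A = list(Ctrl = rep(30e3, 3)),
                      between_sample_cv = list(Ctrl = c(H = 0.5, k = 0.4)))
  ds <- gen_relaxation_dataset(cfg, n_per_group = c(Ctrl = 1), seed = 8,
                               sample_variation = FALSE)
  trace <- ds$traces[[1L]]
  # NaN out almost all of the second hold (leaving < 30 finite samples)
  bad <- trace$time > 60 + 255 + 7 & trace$time < 60 + 2 * 255 - 12
  trace$load[bad] <- NaN
  fit <- fit_sample(trace, program = cfg$program)
  expect_equal(nrow(fit), 3L)
  expect_true(fit$converged[1L] && fit$converged[3L])
  expect_false(fit$converged[2L])
})

test_that("estimates stay accurate under 2% multiplicative load noise", {
  # scaled-down replicate study (8 replicates for runtime; the full design
  # uses 50) checking median bias and spread of the recovered parameters
  truth <- fix_params_fast()
  H <- k <- numeric(8L)
  for (i in seq_len(8L)) {
    cfg <- fix_single_step_config(truth, ramp = 5, hold = 300, noise = 0.02)
    ds <- gen_relaxation_dataset(cfg, n_per_group = c(RA = 1), seed = 100 + i,
                                 sample_variation = FALSE)
    fit <- fit_sample(ds$traces[[1L]], program = cfg$program)
    H[i] <- fit$H_plus_A_Pa[1L]; k[i] <- fit$k_m4_per_Ns[1L]
  }
  expect_lt(abs(stats::median(H) / truth$H_plus_A - 1), 0.02)
  expect_lt(abs(stats::median(k) / truth$k - 1), 0.02)
  expect_lt(stats::sd(H) / mean(H), 0.10)
  expect_lt(stats::sd(k) / mean(k), 0.10)
})

test_that("traces round-trip through CSV + JSON sidecar", {
  cfg <- fix_single_step_config(fix_params_fast(), ramp = 5, hold = 300)
  ds <- gen_relaxation_dataset(cfg, n_per_group = c(RA = 1), seed = 9,
                               sample_variation = FALSE)
  path <- tempfile(fileext = ".csv")
  write_trace(ds$traces[[1L]], path)
  back <- read_trace(path)
  expect_equal(back$load, ds$traces[[1L]]$load, tolerance = 1e-9)
  expect_equal(back$initial_gap, ds$traces[[1L]]$initial_gap)
  expect_equal(back$sample_id, ds$traces[[1L]]$sample_id)
})
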