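# Turning raw load-displacement traces into per-step (H+A, k, H-A)
# estimates: tare handling, step segmentation, equilibrium detection and
# nonlinear least-squares fitting against the forward model.

#' Detect the tare phase and post-tare thickness
#'
#' Locates the point where the trace first reaches the tare load, then the
#' end of the quiescent (constant-displacement) tare equilibrium window
#' preceding the first strain ramp. The post-tare thickness is the platen
#' gap at tare equilibrium (`initial_gap - displacement`). All downstream
#' strains are computed against this thickness.
#'
#' @param trace A [relaxation_trace()] whose `initial_gap` is known.
#' @param tare_load Tare load in newtons. Default `500e-6`.
#' @param drift_tol Maximum tolerated |load slope| (N/s) over the tare
#'   equilibrium window before a drift warning is flagged.
#'
#' @return A list with `thickness` (m), `t_tare_end` (s), and logical
#'   `drift_flagged`.
#' @export
detect_tare_and_thickness <- function(trace, tare_load = 500e-6,
                                      drift_tol = 1e-8) {
  stopifnot(inherits(trace, "relaxation_trace"))
  if (is.na(trace$initial_gap)) stop("trace has no initial_gap metadata")
  hit <- which(trace$load >= tare_load)
  if (!length(hit)) stop("tare never reached")
  i0 <- hit[1L]
  # tare equilibrium ends when the platen starts moving again (first
  # programmed ramp); threshold relative to the largest rate in the trace
  dt <- diff(trace$time)
  rate <- c(diff(trace$displacement) / dt, 0)
  thr <- 0.05 * max(rate, na.rm = TRUE)
  moving <- which(rate > thr & seq_along(rate) > i0)
  i1 <- if (length(moving)) moving[1L] else length(trace$time)
  win <- seq(max(i0, i1 - max(5L, (i1 - i0) %/% 5L)), i1)
  drift <- if (length(win) >= 3L) {
    abs(stats::coef(stats::lm(trace$load[win] ~ trace$time[win]))[2L])
  } else 0
  list(
    thickness = trace$initial_gap - trace$displacement[i1],
    t_tare_end = trace$time[i1],
    drift_flagged = drift > drift_tol
  )
}

#' Segment a trace into ramp-hold strain steps
#'
#' Detects the programmed number of ramps from the displacement rate and
#' returns, for each step, its ramp and hold windows, the measured applied
#' (cumulative) strain, and the equilibrium load (mean load over the final
#' 10% of the hold).
#'
#' @param trace A [relaxation_trace()].
#' @param program The [loading_program()] that was applied.
#' @param thickness Post-tare thickness (m); when `NULL`, taken from
#'   [detect_tare_and_thickness()].
#' @param t_start Time (s) at which the programmed steps may begin (end of
#'   the tare phase); ramps before it are ignored. When `NULL`, taken from
#'   [detect_tare_and_thickness()].
#' @param equilibrium_fraction Fraction of the hold (from the end) averaged
#'   to obtain the equilibrium load. Default 0.1.
#'
#' @return A data frame with one row per step: `index`, `target_strain`,
#'   `applied_strain`, `ramp_start`, `ramp_end`, `hold_start`, `hold_end`,
#'   `equilibrium_load`, `strain_flagged`.
#' @export
segment_steps <- function(trace, program, thickness = NULL, t_start = NULL,
                          equilibrium_fraction = 0.1) {
  stopifnot(inherits(trace, "relaxation_trace"), inherits(program, "loading_program"))
  nstep <- nrow(program$steps)
  if (is.null(thickness) || is.null(t_start)) {
    tare <- detect_tare_and_thickness(trace, program$tare_load)
    if (is.null(thickness)) thickness <- tare$thickness
    t0 <- tare$t_tare_end
  } else {
    t0 <- t_start
  }
  dt <- diff(trace$time)
  rate <- c(diff(trace$displacement) / dt, 0)
  rate[trace$time < t0] <- 0 # tare phase is not a strain step
  thr <- 0.25 * max(rate, na.rm = TRUE)
  if (!is.finite(thr) || thr <= 0) stop("no displacement ramps detected (0 of ",
                                        nstep, " programmed)")
  moving <- rate > thr
  # contiguous runs of motion = ramps
  runs <- rle(moving)
  ends <- cumsum(runs$lengths)
  starts_i <- ends - runs$lengths + 1L
  ramp_runs <- which(runs$values)
  if (length(ramp_runs) < nstep) {
    stop(sprintf("detected %d ramp(s) but program has %d step(s)",
                 length(ramp_runs), nstep))
  }
  ramp_runs <- ramp_runs[seq_len(nstep)]
  disp0 <- trace$displacement[which.min(abs(trace$time - t0))]
  out <- vector("list", nstep)
  for (s in seq_len(nstep)) {
    i_r0 <- starts_i[ramp_runs[s]]
    i_r1 <- ends[ramp_runs[s]] + 1L
    i_r1 <- min(i_r1, length(trace$time))
    i_h1 <- if (s < nstep) starts_i[ramp_runs[s + 1L]] - 1L else length(trace$time)
    hold_t0 <- trace$time[i_r1]
    hold_t1 <- trace$time[i_h1]
    eq_i <- which(trace$time >= hold_t1 - equilibrium_fraction * (hold_t1 - hold_t0) &
                    trace$time <= hold_t1)
    applied <- (trace$displacement[i_r1] - disp0) / thickness
    target <- program$steps$target_strain[s]
    out[[s]] <- data.frame(
      index = s,
      target_strain = target,
      applied_strain = applied,
      ramp_start = trace$time[i_r0],
      ramp_end = hold_t0,
      hold_start = hold_t0,
      hold_end = hold_t1,
      equilibrium_load = mean(trace$load[eq_i], na.rm = TRUE),
      strain_flagged = applied < 0.5 * target || applied > 1.5 * target
    )
  }
  do.call(rbind, out)
}

# Residual vector of the single-step incremental forward model against the
# observed incremental loads. theta = c(log H+A, log k).
step_residuals <- function(theta, t_rel, load_inc, d_strain, ramp, H_minus_A,
                           geom, n_roots) {
  p <- cle_parameters(exp(theta[1L]), H_minus_A, exp(theta[2L]))
  step_load_increment(t_rel, d_strain, ramp, p, geom, n_roots) - load_inc
}

#' Fit the biphasic model to one strain step
#'
#' The equilibrium modulus is obtained in closed form from the incremental
#' equilibrium stress (`H_minus_A = dF_eq / (d_strain * area)`); the
#' transient parameters `(H_plus_A, k)` are then estimated by nonlinear
#' least squares on the incremental load over the step's ramp and hold,
#' with parameters in log-space and a deterministic initialization (`k` from
#' the 63%-relaxation time, `H_plus_A` from the peak/equilibrium ratio) plus
#' fixed multi-start perturbations of +/- half a decade in `k`.
#'
#' @param segment One row of [segment_steps()] output.
#' @param trace The full [relaxation_trace()].
#' @param geom [sample_geometry()] with the post-tare thickness.
#' @param prev_equilibrium_load Load at the previous step's equilibrium (the
#'   tare load for step 1), N.
#' @param prev_strain Cumulative applied strain at the previous step's
#'   equilibrium (0 for step 1).
#' @param n_roots Series terms passed to the forward model.
#' @param drop_first Samples dropped at the start of the ramp (actuator
#'   transients). Default 2.
#'
#' @return A list of class `step_estimate`: `H_plus_A_hat`, `k_hat`,
#'   `H_minus_A_hat` (Pa, Pa and m^4/(N s)), `applied_strain` (cumulative),
#'   `d_strain` (incremental), `rms_residual` (N), `converged`, `reason`.
#' @export
fit_step <- function(segment, trace, geom, prev_equilibrium_load = NULL,
                     prev_strain = 0, n_roots = 80L, drop_first = 2L) {
  stopifnot(inherits(trace, "relaxation_trace"), inherits(geom, "sample_geometry"))
  if (is.null(prev_equilibrium_load)) {
    # mean load just before the ramp
    pre <- trace$time < segment$ramp_start &
      trace$time >= segment$ramp_start - 0.05 * (segment$hold_end - segment$ramp_start)
    prev_equilibrium_load <- if (any(pre)) mean(trace$load[pre], na.rm = TRUE) else trace$load[1L]
  }
  d_strain <- segment$applied_strain - prev_strain
  if (!is.finite(d_strain) || d_strain <= 0) {
    return(failed_estimate(segment, "non-positive incremental strain"))
  }

  idx <- which(trace$time >= segment$ramp_start & trace$time <= segment$hold_end)
  if (length(idx) > drop_first) idx <- idx[-seq_len(drop_first)]
  ok <- is.finite(trace$load[idx])
  idx <- idx[ok]
  n_hold <- sum(trace$time[idx] >= segment$hold_start)
  if (n_hold < 30L) return(failed_estimate(segment, "fewer than 30 hold samples"))

  t_rel <- trace$time[idx] - segment$ramp_start
  load_inc <- trace$load[idx] - prev_equilibrium_load
  ramp <- segment$ramp_end - segment$ramp_start
  eq_inc <- segment$equilibrium_load - prev_equilibrium_load
  if (eq_inc <= 0) return(failed_estimate(segment, "non-positive equilibrium increment"))
  H_minus_A <- eq_inc / (d_strain * geom$area)

  peak <- max(load_inc)
  ratio <- peak / eq_inc
  if (ratio < 1.02) return(failed_estimate(segment, "insufficient transient"))

  # deterministic initialization
  HpA0 <- max(2 * H_minus_A * (ratio - 1), 0.1 * H_minus_A)
  i_peak <- which.max(load_inc)
  post <- idx >= idx[i_peak]
  target63 <- eq_inc + (peak - eq_inc) * exp(-1)
  below <- which(load_inc <= target63 & seq_along(load_inc) >= i_peak)
  t63 <- if (length(below)) t_rel[below[1L]] - t_rel[i_peak] else
    0.25 * (max(t_rel) - t_rel[i_peak])
  t63 <- max(t63, ramp / 2)
  # tau_g ~ t63 * alpha_1^2 gives k ~ a^2/(H+A * alpha_1^2 * t63)
  k0 <- geom$radius^2 / (HpA0 * cle_roots(1L)[1L]^2 * t63)

  obj <- function(theta) {
    r <- step_residuals(theta, t_rel, load_inc, d_strain, ramp, H_minus_A,
                        geom, n_roots)
    sum(r^2)
  }
  starts <- list(c(log(HpA0), log(k0)),
                 c(log(HpA0), log(k0) + log(10) / 2),
                 c(log(HpA0), log(k0) - log(10) / 2),
                 c(log(2 * HpA0), log(k0)))
  # rank the deterministic starts by objective value, then polish the best two
  vals <- vapply(starts, function(th) tryCatch(obj(th), error = function(e) Inf),
                 numeric(1))
  best <- NULL
  for (th0 in starts[order(vals)][1:2]) {
    fit <- tryCatch(
      stats::optim(th0, obj, method = "Nelder-Mead",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    fit <- tryCatch(
      stats::optim(fit$par, obj, method = "BFGS",
                   control = list(maxit = 200, reltol = 1e-14)),
      error = function(e) fit
    )
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) return(failed_estimate(segment, "optimizer failure"))

  structure(list(
    index = segment$index,
    H_plus_A_hat = exp(best$par[1L]),
    k_hat = exp(best$par[2L]),
    H_minus_A_hat = H_minus_A,
    applied_strain = segment$applied_strain,
    d_strain = d_strain,
    rms_residual = sqrt(best$value / length(load_inc)),
    converged = TRUE,
    reason = NA_character_
  ), class = "step_estimate")
}

failed_estimate <- function(segment, reason) {
  structure(list(
    index = segment$index,
    H_plus_A_hat = NA_real_, k_hat = NA_real_, H_minus_A_hat = NA_real_,
    applied_strain = segment$applied_strain,
    d_strain = NA_real_, rms_residual = NA_real_,
    converged = FALSE, reason = reason
  ), class = "step_estimate")
}

#' Fit every strain step of one sample's trace
#'
#' Runs tare detection, segmentation, and per-step fitting; steps are fit
#' independently (incremental strain and incremental load relative to the
#' previous step's equilibrium) and a failure in one step does not abort the
#' others.
#'
#' @param trace A [relaxation_trace()].
#' @param geom A [sample_geometry()], or `NULL` to build one from the
#'   detected post-tare thickness and the default punch radius.
#' @param program The [loading_program()] applied.
#' @param ... Passed to [fit_step()].
#'
#' @return A data frame of class `sample_fit` with one row per step
#'   (columns as in [fit_step()] plus `sample_id`).
#' @export
fit_sample <- function(trace, geom = NULL, program = loading_program(), ...) {
  tare <- detect_tare_and_thickness(trace, program$tare_load)
  if (is.null(geom)) geom <- sample_geometry(thickness = tare$thickness)
  segs <- segment_steps(trace, program, thickness = tare$thickness,
                        t_start = tare$t_tare_end)
  prev_load <- program$tare_load
  prev_strain <- 0
  rows <- vector("list", nrow(segs))
  for (s in seq_len(nrow(segs))) {
    est <- tryCatch(
      fit_step(segs[s, ], trace, geom,
               prev_equilibrium_load = prev_load,
               prev_strain = prev_strain, ...),
      error = function(e) failed_estimate(segs[s, ], conditionMessage(e))
    )
    rows[[s]] <- data.frame(
      sample_id = trace$sample_id,
      step = est$index,
      strain_applied = est$applied_strain,
      H_plus_A_Pa = est$H_plus_A_hat,
      k_m4_per_Ns = est$k_hat,
      H_minus_A_Pa = est$H_minus_A_hat,
      rms_residual_N = est$rms_residual,
      converged = est$converged,
      reason = est$reason
    )
    # advance the baseline even past failed steps, using measured values
    prev_load <- segs$equilibrium_load[s]
    prev_strain <- segs$applied_strain[s]
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sample_fit", class(out))
  out
}

#' Write and read relaxation traces as CSV + JSON sidecar
#'
#' Traces are serialized with header columns `time_s`, `displacement_um`,
#' `load_uN` and a JSON sidecar holding `sample_id`, `initial_gap_m`,
#' `temperature_C`. Loaders convert back to SI.
#'
#' @param trace A [relaxation_trace()].
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   [relaxation_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "relaxation_trace"))
  utils::write.csv(
    data.frame(time_s = trace$time,
               displacement_um = trace$displacement * 1e6,
               load_uN = trace$load * 1e6),
    path, row.names = FALSE
  )
  jsonlite::write_json(
    list(sample_id = trace$sample_id, initial_gap_m = trace$initial_gap,
         temperature_C = trace$temperature),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  relaxation_trace(
    time = df$time_s,
    displacement = df$displacement_um * 1e-6,
    load = df$load_uN * 1e-6,
    sample_id = meta$sample_id,
    temperature = meta$temperature_C,
    initial_gap = meta$initial_gap_m
  )
}
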