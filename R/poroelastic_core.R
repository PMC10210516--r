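# Internal cache for characteristic roots of the unconfined-compression
# eigenproblem (shared by every series evaluation in a session).
.sclerafit_env <- new.env(parent = emptyenv())

#' Cylindrical sample geometry
#'
#' Geometry of a cylindrical tissue button tested in unconfined compression,
#' as obtained with a biopsy punch. The default radius corresponds to a
#' 1-mm-diameter punch.
#'
#' @param radius Sample radius in metres (> 0). Default `0.5e-3`.
#' @param thickness Post-tare sample thickness in metres (> 0).
#'
#' @return An object of class `sample_geometry` with fields `radius`,
#'   `thickness` and the derived cross-sectional `area` (m^2).
#' @examples
#' geom <- sample_geometry(thickness = 200e-6)
#' geom$area # pi * (0.5 mm)^2
#' @export
sample_geometry <- function(radius = 0.5e-3, thickness) {
  stopifnot(is.numeric(radius), length(radius) == 1L, is.finite(radius))
  stopifnot(is.numeric(thickness), length(thickness) == 1L, is.finite(thickness))
  if (radius <= 0) stop("radius must be > 0")
  if (thickness <= 0) stop("thickness must be > 0")
  structure(
    list(radius = radius, thickness = thickness, area = pi * radius^2),
    class = "sample_geometry"
  )
}

#' Conewise-linear-elastic biphasic material parameters
#'
#' Material parameters of the biphasic (poroelastic) model with
#' tension-compression nonlinearity used for scleral buttons in unconfined
#' compression: through-plane compression puts the in-plane (radial/hoop)
#' fibres in tension, so the transient is governed by the aggregate *tensile*
#' modulus `H_plus_A` and hydraulic conductivity `k`, while the equilibrium
#' response is governed by the axial aggregate *compressive* modulus
#' `H_minus_A`.
#'
#' @param H_plus_A In-plane (radial/circumferential) aggregate tensile
#'   modulus, Pa (> 0).
#' @param H_minus_A Axial aggregate compressive (equilibrium) modulus,
#'   Pa (> 0).
#' @param k Hydraulic conductivity in m^4 N^-1 s^-1 (equivalently
#'   m^2 Pa^-1 s^-1; > 0).
#' @param lambda_offdiag Off-diagonal coupling modulus, Pa (>= 0). The
#'   solvers in this package implement the uncoupled case and refuse nonzero
#'   values; the field exists so data structures can carry the more general
#'   material description.
#'
#' @return An object of class `cle_parameters`.
#' @examples
#' cle_parameters(H_plus_A = 104e3, H_minus_A = 30e3, k = 9.6e-15)
#' @export
cle_parameters <- function(H_plus_A, H_minus_A, k, lambda_offdiag = 0) {
  vals <- c(H_plus_A, H_minus_A, k, lambda_offdiag)
  stopifnot(is.numeric(vals), length(vals) == 4L, all(is.finite(vals)))
  if (H_plus_A <= 0) stop("H_plus_A must be > 0")
  if (H_minus_A <= 0) stop("H_minus_A must be > 0")
  if (k <= 0) stop("k must be > 0")
  if (lambda_offdiag < 0) stop("lambda_offdiag must be >= 0")
  structure(
    list(H_plus_A = H_plus_A, H_minus_A = H_minus_A, k = k,
         lambda_offdiag = lambda_offdiag),
    class = "cle_parameters"
  )
}

#' Ramp-and-hold loading program
#'
#' The displacement-controlled protocol applied after the tare load:
#' incremental compressive strain steps, each a finite-duration linear ramp
#' followed by a hold to equilibrium. Strains are engineering compressive
#' strains relative to the post-tare thickness and *cumulative* across steps
#' (defaults 5/10/15%).
#'
#' @param target_strains Cumulative strain targets, strictly increasing, all
#'   in (0, 0.5). Default `c(0.05, 0.10, 0.15)`.
#' @param ramp_duration Ramp duration per step, s (> 0). Default 10.
#' @param hold_duration Hold duration per step, s (> 0). Default 1500.
#' @param tare_load Tare preload in newtons. Default `500e-6` (500 uN).
#'
#' @return An object of class `loading_program` whose `steps` element is a
#'   data frame with columns `target_strain`, `ramp_duration`,
#'   `hold_duration`.
#' @export
loading_program <- function(target_strains = c(0.05, 0.10, 0.15),
                            ramp_duration = 10,
                            hold_duration = 1500,
                            tare_load = 500e-6) {
  stopifnot(is.numeric(target_strains), length(target_strains) >= 1L)
  if (any(diff(target_strains) <= 0)) stop("target strains must be strictly increasing")
  if (any(target_strains <= 0 | target_strains >= 0.5)) {
    stop("target strains must lie in (0, 0.5)")
  }
  nstep <- length(target_strains)
  ramp_duration <- rep_len(ramp_duration, nstep)
  hold_duration <- rep_len(hold_duration, nstep)
  if (any(ramp_duration <= 0) || any(hold_duration <= 0)) {
    stop("ramp and hold durations must be > 0")
  }
  structure(
    list(
      tare_load = tare_load,
      steps = data.frame(
        target_strain = target_strains,
        ramp_duration = ramp_duration,
        hold_duration = hold_duration
      )
    ),
    class = "loading_program"
  )
}

#' Stress-relaxation trace
#'
#' A time-stamped record of one unconfined-compression test: platen position
#' (compression positive, zero at trace start) and axial load.
#'
#' @param time Time stamps, s, strictly increasing.
#' @param displacement Platen displacement, m, compression positive.
#' @param load Axial load, N.
#' @param sample_id Sample identifier string.
#' @param temperature Bath temperature, degrees C (metadata). Default 37.
#' @param initial_gap Platen separation at trace start, m, or `NA` when
#'   unknown. Needed to convert tare displacement into post-tare thickness.
#'
#' @return An object of class `relaxation_trace`.
#' @export
relaxation_trace <- function(time, displacement, load, sample_id = "sample",
                             temperature = 37, initial_gap = NA_real_) {
  n <- length(time)
  if (length(displacement) != n || length(load) != n) {
    stop("time, displacement and load must have equal length")
  }
  if (n >= 2L && any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (any(!is.finite(load) & !is.na(load))) stop("load must be finite or NA")
  structure(
    list(time = as.numeric(time), displacement = as.numeric(displacement),
         load = as.numeric(load), sample_id = as.character(sample_id),
         temperature = temperature, initial_gap = initial_gap),
    class = "relaxation_trace"
  )
}

# Characteristic roots alpha_n of J1(x) = x J0(x) (the zeros of J1'),
# bracketed between consecutive zeros of J0 and refined by bisection.
cle_roots <- function(n_roots = 200L) {
  cached <- .sclerafit_env$roots
  if (!is.null(cached) && length(cached) >= n_roots) return(cached[seq_len(n_roots)])
  j0zero <- function(m) {
    uniroot(function(x) besselJ(x, 0), c((m - 0.75) * pi, (m + 0.25) * pi),
            tol = 1e-14)$root
  }
  g <- function(x) besselJ(x, 1) - x * besselJ(x, 0)
  z <- vapply(seq_len(n_roots + 1L), j0zero, numeric(1))
  roots <- numeric(n_roots)
  roots[1] <- uniroot(g, c(1e-8, z[1] - 1e-9), tol = 1e-14)$root
  for (m in seq(2L, n_roots)) {
    roots[m] <- uniroot(g, c(z[m - 1] + 1e-9, z[m] - 1e-9), tol = 1e-14)$root
  }
  .sclerafit_env$roots <- roots
  roots
}

check_uncoupled <- function(params) {
  if (params$lambda_offdiag != 0) {
    stop("solvers implement the uncoupled material (lambda_offdiag = 0) only")
  }
  invisible(params)
}

#' Equilibrium load of a compressive strain step
#'
#' At equilibrium all interstitial fluid pressure has dissipated and the
#' axial load is carried by the solid matrix alone, so (with zero
#' off-diagonal coupling) the load is `H_minus_A * strain * area`,
#' independent of `H_plus_A` and `k`.
#'
#' @param params [cle_parameters()] object.
#' @param strain Cumulative engineering compressive strain, in (0, 0.5).
#' @param geom [sample_geometry()] object.
#'
#' @return Equilibrium load in newtons.
#' @examples
#' geom <- sample_geometry(thickness = 200e-6)
#' p <- cle_parameters(104e3, 100e3, 9.6e-15)
#' equilibrium_load(p, 0.05, geom) # 100e3 * 0.05 * pi * (0.5e-3)^2
#' @export
equilibrium_load <- function(params, strain, geom) {
  stopifnot(inherits(params, "cle_parameters"), inherits(geom, "sample_geometry"))
  check_uncoupled(params)
  if (!is.numeric(strain) || any(strain <= 0) || any(strain >= 0.5)) {
    stop("strain must lie in (0, 0.5)")
  }
  params$H_minus_A * strain * geom$area
}

#' Characteristic (gel diffusion) time
#'
#' The relaxation timescale of the radial fluid-flow problem,
#' `radius^2 / (H_plus_A * k)`.
#'
#' @inheritParams equilibrium_load
#' @return Time in seconds.
#' @examples
#' characteristic_time(cle_parameters(100e3, 30e3, 1e-14),
#'                     sample_geometry(thickness = 2e-4)) # 250 s
#' @export
characteristic_time <- function(params, geom) {
  stopifnot(inherits(params, "cle_parameters"), inherits(geom, "sample_geometry"))
  geom$radius^2 / (params$H_plus_A * params$k)
}

# Load response (N) of a single incremental ramp-hold step, evaluated at
# times t (s, relative to ramp start; t < 0 gives 0). Duhamel superposition
# of the step response over a linear displacement ramp of duration t_r:
#   F_step(t) = pi a^2 eps [ H-A + H+A sum_n exp(-alpha_n^2 t/tau)/(alpha_n^2-1) ]
# integrated against the constant ramp rate. tau = a^2/(H+A k).
step_load_increment <- function(t, d_strain, ramp, params, geom,
                                n_roots = 200L) {
  a <- geom$radius
  tau <- a^2 / (params$H_plus_A * params$k)
  area <- geom$area
  al2 <- cle_roots(n_roots)^2
  coef <- (tau / al2) / (al2 - 1)
  out <- numeric(length(t))

  in_ramp <- t >= 0 & t <= ramp
  if (any(in_ramp)) {
    tt <- t[in_ramp]
    S <- colSums(coef * (1 - exp(-outer(al2 / tau, tt))))
    out[in_ramp] <- area * (d_strain / ramp) *
      (params$H_minus_A * tt + params$H_plus_A * S)
  }
  in_hold <- t > ramp
  if (any(in_hold)) {
    tt <- t[in_hold]
    S <- colSums(coef * (exp(-outer(al2 / tau, tt - ramp)) -
                           exp(-outer(al2 / tau, tt))))
    out[in_hold] <- area * d_strain * params$H_minus_A +
      area * (d_strain / ramp) * params$H_plus_A * S
  }
  out
}

program_times <- function(program, sampling_rate) {
  durations <- program$steps$ramp_duration + program$steps$hold_duration
  total <- sum(durations)
  seq(0, total, by = 1 / sampling_rate)
}

#' Simulate an unconfined-compression stress-relaxation test
#'
#' Semi-analytic forward model of the axisymmetric linear biphasic problem
#' (radial fluid flow, free-draining lateral edge, frictionless impermeable
#' platens): the load history of a sequence of ramp-and-hold compressive
#' strain steps, obtained by Duhamel superposition of the Bessel-series step
#' response. The trace starts at the end of the tare phase (load offset
#' `program$tare_load`, displacement zero).
#'
#' @inheritParams equilibrium_load
#' @param program [loading_program()] object.
#' @param sampling_rate Samples per second. Must resolve each ramp with at
#'   least 2 samples.
#' @param n_roots Number of series terms (characteristic roots).
#' @param sample_id Identifier stored in the returned trace.
#'
#' @return A [relaxation_trace()]; the load includes the tare offset and the
#'   displacement is the platen travel past the tare position.
#' @export
simulate_response <- function(params, geom, program, sampling_rate = 1,
                              n_roots = 200L, sample_id = "sim") {
  stopifnot(inherits(params, "cle_parameters"), inherits(geom, "sample_geometry"),
            inherits(program, "loading_program"))
  check_uncoupled(params)
  if (any(sampling_rate * program$steps$ramp_duration < 2)) {
    stop("sampling_rate too low: need >= 2 samples per ramp")
  }
  tgrid <- program_times(program, sampling_rate)
  starts <- cumsum(c(0, utils::head(program$steps$ramp_duration +
                                      program$steps$hold_duration, -1)))
  d_strains <- diff(c(0, program$steps$target_strain))
  load <- rep(program$tare_load, length(tgrid))
  strain <- numeric(length(tgrid))
  for (s in seq_len(nrow(program$steps))) {
    rel_t <- tgrid - starts[s]
    load <- load + step_load_increment(rel_t, d_strains[s],
                                       program$steps$ramp_duration[s],
                                       params, geom, n_roots)
    strain <- strain + d_strains[s] *
      pmin(pmax(rel_t, 0) / program$steps$ramp_duration[s], 1)
  }
  relaxation_trace(
    time = tgrid,
    displacement = strain * geom$thickness,
    load = load,
    sample_id = sample_id,
    initial_gap = geom$thickness
  )
}

#' Finite-difference reference solver for the biphasic problem
#'
#' Independent normative cross-check for [simulate_response()]: an implicit
#' (backward Euler) finite-difference solution of the radial diffusion
#' equation satisfied by the areal strain `e(r, t)`, with the nonlocal
#' boundary condition implied by zero radial stress and zero pressure at the
#' free-draining edge. No Bessel functions or series are involved.
#'
#' @inheritParams simulate_response
#' @param n_radial Number of radial intervals (>= 50).
#' @param dt Time step, s. Defaults to the smaller of `ramp/20` and
#'   `tau_g/400`.
#'
#' @return A [relaxation_trace()] on the same sampling grid as
#'   [simulate_response()].
#' @export
fd_oracle_response <- function(params, geom, program, sampling_rate = 1,
                               n_radial = 150L, dt = NULL) {
  stopifnot(inherits(params, "cle_parameters"), inherits(geom, "sample_geometry"),
            inherits(program, "loading_program"))
  check_uncoupled(params)
  if (n_radial < 50L) stop("n_radial must be >= 50")
  a <- geom$radius
  D <- params$k * params$H_plus_A
  tau <- a^2 / D
  if (is.null(dt)) dt <- min(min(program$steps$ramp_duration) / 20, tau / 400)
  if (dt <= 0 || !is.finite(dt)) stop("dt must be positive and finite")

  N <- as.integer(n_radial)
  dr <- a / N
  r <- (0:N) * dr
  L <- matrix(0, N + 1L, N + 1L)
  for (i in 2:N) {
    ri <- r[i]
    L[i, i - 1L] <- (ri - dr / 2) / (ri * dr^2)
    L[i, i + 1L] <- (ri + dr / 2) / (ri * dr^2)
    L[i, i] <- -2 / dr^2
  }
  L[1L, 1L] <- -4 / dr^2
  L[1L, 2L] <- 4 / dr^2
  A1 <- diag(N + 1L) - dt * D * L
  # nonlocal BC: e(a) = (1/a^2) * integral_0^a e r dr  (trapezoid weights)
  w <- rep(dr, N + 1L); w[1L] <- w[N + 1L] <- dr / 2
  bc <- -(w * r) / a^2
  bc[N + 1L] <- bc[N + 1L] + 1
  A1[N + 1L, ] <- bc
  Ainv <- solve(A1)

  tgrid <- program_times(program, sampling_rate)
  starts <- cumsum(c(0, utils::head(program$steps$ramp_duration +
                                      program$steps$hold_duration, -1)))
  d_strains <- diff(c(0, program$steps$target_strain))
  strain_of_t <- function(t) {
    eps <- numeric(length(t))
    for (s in seq_len(nrow(program$steps))) {
      eps <- eps + d_strains[s] *
        pmin(pmax(t - starts[s], 0) / program$steps$ramp_duration[s], 1)
    }
    eps
  }

  nt <- ceiling(max(tgrid) / dt)
  tfd <- (0:nt) * dt
  epsg <- strain_of_t(tfd)
  e <- numeric(N + 1L)
  eN <- numeric(nt + 1L)
  for (m in seq_len(nt)) {
    b <- e + (epsg[m + 1L] - epsg[m])
    b[N + 1L] <- 0
    e <- Ainv %*% b
    if (any(!is.finite(e))) {
      stop(sprintf("finite-difference solution diverged at step %d (t = %.3f s)",
                   m, tfd[m + 1L]))
    }
    eN[m + 1L] <- e[N + 1L]
  }
  Ffd <- geom$area * (params$H_minus_A * epsg + params$H_plus_A * eN) +
    program$tare_load
  load <- approx(tfd, Ffd, xout = tgrid, rule = 2)$y
  relaxation_trace(
    time = tgrid,
    displacement = strain_of_t(tgrid) * geom$thickness,
    load = load,
    sample_id = "fd_oracle",
    initial_gap = geom$thickness
  )
}
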