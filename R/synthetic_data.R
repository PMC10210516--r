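# Seeded generators for every input the pipeline consumes: stress-relaxation
# traces from the biphasic forward model, a two-arm longitudinal biometry
# cohort, linear-response assay plates, and two-channel masked intensity
# images. Every generator requires a seed and emits its ground truth so
# recovery can be scored automatically.

#' Configuration for synthetic relaxation traces
#'
#' Per-group ground-truth material parameters per strain step. Defaults are
#' centred on the group means measured in atRA-treated and control mouse
#' sclera (treated: `H_plus_A` 104 kPa, `k` 0.96e-14 m^4/(N s); control:
#' 160 kPa, 0.73e-14), with linear strain trends such that the treated
#' sclera stiffens less and loses less conductivity with compression than
#' control sclera, and a flat 30 kPa equilibrium modulus.
#'
#' @param H_plus_A Named list of per-step tensile moduli (Pa) per group.
#' @param k Named list of per-step conductivities (m^4/(N s)) per group.
#' @param H_minus_A Named list of per-step equilibrium moduli (Pa).
#' @param between_sample_cv Lognormal coefficient of variation of the
#'   per-sample parameter multipliers (applied jointly to all steps of a
#'   sample). Defaults approximate the printed between-eye SDs
#'   (H: 47/104 for treated, 96/160 for control; the k CVs likewise).
#' @param geometry [sample_geometry()] of generated samples.
#' @param program [loading_program()] applied.
#' @param load_noise_sd Multiplicative load noise SD (fraction). Default 0.
#' @param floor_noise_N Additive sensor-floor noise SD (N). Default 0.
#' @param sampling_rate Hz. Default 1.
#' @param tare_displacement Platen travel during tare, m. Default 10e-6.
#'
#' @return A list of class `trace_config`.
#' @export
trace_config <- function(
    H_plus_A = list(Ctrl = c(100e3, 160e3, 220e3), RA = c(78e3, 104e3, 130e3)),
    k = list(Ctrl = c(1.00e-14, 0.73e-14, 0.46e-14),
             RA = c(1.10e-14, 0.96e-14, 0.82e-14)),
    H_minus_A = list(Ctrl = c(30e3, 30e3, 30e3), RA = c(30e3, 30e3, 30e3)),
    between_sample_cv = list(Ctrl = c(H = 0.6, k = 0.4),
                             RA = c(H = 0.45, k = 0.4)),
    geometry = sample_geometry(thickness = 200e-6),
    program = loading_program(),
    load_noise_sd = 0,
    floor_noise_N = 0,
    sampling_rate = 1,
    tare_displacement = 10e-6) {
  nstep <- nrow(program$steps)
  for (g in names(H_plus_A)) {
    if (length(H_plus_A[[g]]) != nstep || length(k[[g]]) != nstep ||
        length(H_minus_A[[g]]) != nstep) {
      stop("per-step truth vectors must match the number of program steps")
    }
    if (any(H_plus_A[[g]] <= 0) || any(k[[g]] <= 0) || any(H_minus_A[[g]] <= 0)) {
      stop("inadmissible ground-truth parameters (must be > 0)")
    }
  }
  if (load_noise_sd < 0 || floor_noise_N < 0) stop("noise SDs must be >= 0")
  structure(list(
    H_plus_A = H_plus_A, k = k, H_minus_A = H_minus_A,
    between_sample_cv = between_sample_cv,
    geometry = geometry, program = program,
    load_noise_sd = load_noise_sd, floor_noise_N = floor_noise_N,
    sampling_rate = sampling_rate, tare_displacement = tare_displacement
  ), class = "trace_config")
}

# Build one synthetic trace (tare phase + programmed steps) for given
# per-step true parameters. Steps are superposed incrementally, each with
# its own step parameters (the per-step linearization the fitting assumes).
synthesize_trace <- function(step_params, config, sample_id) {
  geom <- config$geometry
  program <- config$program
  fs <- config$sampling_rate
  tare_ramp <- 10; tare_hold <- 50
  t_tare <- seq(0, tare_ramp + tare_hold, by = 1 / fs)
  d_tare <- config$tare_displacement * pmin(t_tare / tare_ramp, 1)
  load_tare <- program$tare_load * pmin(t_tare / tare_ramp, 1)

  t_prog <- program_times(program, fs)
  starts <- cumsum(c(0, utils::head(program$steps$ramp_duration +
                                      program$steps$hold_duration, -1)))
  d_strains <- diff(c(0, program$steps$target_strain))
  load <- rep(program$tare_load, length(t_prog))
  strain <- numeric(length(t_prog))
  for (s in seq_len(nrow(program$steps))) {
    p <- step_params[[s]]
    rel_t <- t_prog - starts[s]
    load <- load + step_load_increment(rel_t, d_strains[s],
                                       program$steps$ramp_duration[s], p, geom)
    strain <- strain + d_strains[s] *
      pmin(pmax(rel_t, 0) / program$steps$ramp_duration[s], 1)
  }
  time <- c(t_tare, t_prog[-1L] + max(t_tare))
  disp <- c(d_tare, config$tare_displacement + strain[-1L] * geom$thickness)
  load_all <- c(load_tare, load[-1L])
  if (config$load_noise_sd > 0) {
    load_all <- load_all * (1 + stats::rnorm(length(load_all), 0, config$load_noise_sd))
  }
  if (config$floor_noise_N > 0) {
    load_all <- load_all + stats::rnorm(length(load_all), 0, config$floor_noise_N)
  }
  relaxation_trace(
    time = time, displacement = disp, load = load_all, sample_id = sample_id,
    initial_gap = geom$thickness + config$tare_displacement
  )
}

#' Generate a synthetic unconfined-compression dataset
#'
#' Produces noiseless-or-noisy stress-relaxation traces from the biphasic
#' forward model for a two-arm design, together with a ground-truth table
#' for recovery scoring. Deterministic given `seed`.
#'
#' @param config A [trace_config()].
#' @param n_per_group Named counts of samples per group. Default
#'   `c(Ctrl = 8, RA = 10)`, the unconfined-compression arm sizes.
#' @param seed Mandatory integer seed.
#' @param sample_variation Draw per-sample lognormal parameter multipliers
#'   (default TRUE); set FALSE for exact group-mean truths.
#'
#' @return A list with `traces` (list of [relaxation_trace()]) and `truth`
#'   (data frame: sample_id, group, step, true parameters).
#' @export
gen_relaxation_dataset <- function(config = trace_config(),
                                   n_per_group = c(Ctrl = 8, RA = 10),
                                   seed, sample_variation = TRUE) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(inherits(config, "trace_config"))
  set.seed(seed)
  traces <- list(); truth <- list()
  nstep <- nrow(config$program$steps)
  for (g in names(n_per_group)) {
    for (i in seq_len(n_per_group[[g]])) {
      id <- sprintf("%s_%02d", g, i)
      cv <- config$between_sample_cv[[g]]
      mH <- if (sample_variation) stats::rlnorm(1, -0.5 * log(1 + cv[["H"]]^2),
                                                sqrt(log(1 + cv[["H"]]^2))) else 1
      mk <- if (sample_variation) stats::rlnorm(1, -0.5 * log(1 + cv[["k"]]^2),
                                                sqrt(log(1 + cv[["k"]]^2))) else 1
      sp <- lapply(seq_len(nstep), function(s) {
        cle_parameters(config$H_plus_A[[g]][s] * mH,
                       config$H_minus_A[[g]][s] * mH,
                       config$k[[g]][s] * mk)
      })
      traces[[id]] <- synthesize_trace(sp, config, id)
      truth[[id]] <- data.frame(
        sample_id = id, group = g, step = seq_len(nstep),
        H_plus_A_true = vapply(sp, `[[`, 0, "H_plus_A"),
        k_true = vapply(sp, `[[`, 0, "k"),
        H_minus_A_true = vapply(sp, `[[`, 0, "H_minus_A")
      )
    }
  }
  list(traces = traces, truth = do.call(rbind, c(truth, make.row.names = FALSE)))
}

#' Configuration for a synthetic longitudinal cohort
#'
#' Two-arm design (control n = 14, treated n = 16; baseline, 1-week and
#' 2-week timepoints) with per-outcome baseline means, control-group drifts,
#' and treated offsets. Default drifts and offsets are the measured group
#' effects: e.g. treated VCD shifts of +20.7 and +32.3 um, refractive-error
#' shifts of -3.7 and -5.7 D, control axial-length growth of 82.6 and
#' 132.1 um versus 90.9 and 145.0 um in treated animals. Noise is split
#' into a between-animal intercept (`sd_animal`), an animal-by-timepoint
#' component (`sd_time`), a between-eye residual (`sd_eye`), and a
#' treated-response heterogeneity proportional to the offset
#' (`response_cv`); the default SDs reproduce the printed 2-week shift and
#' delta SDs approximately.
#'
#' @param n Named group sizes. Default `c(Ctrl = 14, RA = 16)`.
#' @param timepoints Timepoint labels. Default `c("t0", "t1wk", "t2wk")`.
#' @param ages Nominal age (days) at each timepoint. Default `c(28, 35, 42)`.
#' @param age_jitter_sd SD of per-animal-timepoint age deviation, days.
#' @param outcomes Named list of per-outcome settings; each element has
#'   `baseline`, `drift` (length 3, control mean trajectory), `offset`
#'   (length 3, treated minus control), `sd_animal`, `sd_time`, `sd_eye`,
#'   `response_cv`, and `positive` (truncate at 3 SD above zero).
#' @param seed Ignored here (the generator takes its own seed) but kept so
#'   configs can record one.
#'
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n = c(Ctrl = 14, RA = 16),
                          timepoints = c("t0", "t1wk", "t2wk"),
                          ages = c(28, 35, 42),
                          age_jitter_sd = 0.5,
                          outcomes = default_cohort_outcomes(),
                          seed = NULL) {
  if (any(n < 1)) stop("group sizes must be >= 1")
  for (o in names(outcomes)) {
    oc <- outcomes[[o]]
    if (length(oc$drift) != length(timepoints) ||
        length(oc$offset) != length(timepoints)) {
      stop("drift/offset must have one value per timepoint for outcome ", o)
    }
    if (any(c(oc$sd_animal, oc$sd_time, oc$sd_eye) < 0)) {
      stop("SDs must be >= 0 for outcome ", o)
    }
  }
  structure(list(n = n, timepoints = timepoints, ages = ages,
                 age_jitter_sd = age_jitter_sd, outcomes = outcomes,
                 seed = seed),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_cohort_outcomes <- function() {
  list(
    # lengths in um; RE in diopters. drift = control mean change from
    # baseline; offset = treated - control at each timepoint.
    RE  = list(baseline = 2.5, drift = c(0, 0.5, 1.0),
               offset = c(0, -3.7, -5.7),
               sd_animal = 0.8, sd_time = 0.6, sd_eye = 0.7,
               response_cv = 0.33, positive = FALSE),
    VCD = list(baseline = 830, drift = c(0, -25.2, -45.1),
               offset = c(0, 20.7, 32.3),
               sd_animal = 10, sd_time = 8, sd_eye = 10,
               response_cv = 0.6, positive = TRUE),
    AL  = list(baseline = 3320, drift = c(0, 82.6, 132.1),
               offset = c(0, 8.3, 12.9),
               sd_animal = 32, sd_time = 8, sd_eye = 10,
               response_cv = 0.35, positive = TRUE),
    ACD = list(baseline = 320, drift = c(0, 19.9, 35.7),
               offset = c(0, -8.8, -9.0),
               sd_animal = 10, sd_time = 4, sd_eye = 6,
               response_cv = 0.35, positive = TRUE),
    CCT = list(baseline = 95, drift = c(0, 1, 2),
               offset = c(0, 0, 0),
               sd_animal = 3, sd_time = 1.5, sd_eye = 2,
               response_cv = 0, positive = TRUE),
    LT  = list(baseline = 1850, drift = c(0, 60, 110),
               offset = c(0, 0, 0),
               sd_animal = 15, sd_time = 6, sd_eye = 8,
               response_cv = 0, positive = TRUE),
    RT  = list(baseline = 225, drift = c(0, -2, -4),
               offset = c(0, 0, 0),
               sd_animal = 5, sd_time = 2, sd_eye = 3,
               response_cv = 0, positive = TRUE)
  )
}

#' Generate a synthetic longitudinal biometry/refraction cohort
#'
#' Draws a long-format table (animal x eye x timepoint x outcome) from the
#' additive model described in [cohort_config()]. The expected eye-averaged
#' treated-minus-control shift at each timepoint equals the configured
#' offset, and the expected control change from baseline equals the
#' configured drift.
#'
#' @param config A [cohort_config()].
#' @param seed Mandatory integer seed.
#'
#' @return A list with `data` (long table: animal_id, eye, treatment,
#'   timepoint, age_days, outcome, value, excluded, reason) and `truth`
#'   (the configured offsets/drifts per outcome and timepoint).
#' @export
gen_cohort <- function(config = cohort_config(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  tps <- config$timepoints
  ntp <- length(tps)
  rows <- list()
  truth <- list()
  for (g in names(config$n)) {
    treated <- g != "Ctrl"
    for (i in seq_len(config$n[[g]])) {
      id <- sprintf("%s_%02d", g, i)
      age <- rep(config$ages + stats::rnorm(ntp, 0, config$age_jitter_sd),
                 each = 2L)
      for (o in names(config$outcomes)) {
        oc <- config$outcomes[[o]]
        b_i <- stats::rnorm(1, 0, oc$sd_animal)
        # per-animal response heterogeneity scales the whole offset profile
        resp <- if (treated && oc$response_cv > 0) {
          stats::rnorm(1, 1, oc$response_cv)
        } else 1
        c_it <- stats::rnorm(ntp, 0, oc$sd_time)
        mu <- oc$baseline + b_i + oc$drift +
          (if (treated) resp * oc$offset else 0) + c_it
        val <- rep(mu, each = 2L) + stats::rnorm(2L * ntp, 0, oc$sd_eye)
        if (isTRUE(oc$positive)) val <- pmax(val, oc$baseline / 100)
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = id, eye = rep(c("OD", "OS"), times = ntp),
          treatment = g, timepoint = rep(tps, each = 2L),
          age_days = age, outcome = o, value = val,
          excluded = FALSE, reason = NA_character_
        )
      }
    }
  }
  for (o in names(config$outcomes)) {
    oc <- config$outcomes[[o]]
    truth[[o]] <- data.frame(
      outcome = o, timepoint = tps, drift = oc$drift, offset = oc$offset
    )
  }
  list(data = do.call(rbind, c(rows, make.row.names = FALSE)),
       truth = do.call(rbind, c(truth, make.row.names = FALSE)))
}

#' Generate a synthetic spectrophotometric assay plate
#'
#' Standards plus triplicate sample absorbances from a linear response
#' `A = slope * C + intercept` with optional gaussian noise. Ground truth
#' (per-sample digest concentrations) is returned alongside.
#'
#' @param true_mass_fractions Named numeric vector of true analyte mass
#'   fractions (ug analyte per mg tissue), one per sample.
#' @param dry_mass_mg Named or unnamed dry masses (mg), recycled.
#' @param digest_volume_uL Digest volume, uL. Default 200.
#' @param working_range Standard working range (assay units). Default
#'   `c(0, 4)` (the DNA range; use `c(0, 25)` for sGAG).
#' @param n_standards Number of standards. Default 8.
#' @param slope,intercept Linear response parameters. Defaults 0.2, 0.05.
#' @param noise_sd Absorbance noise SD. Default 0.
#' @param seed Mandatory integer seed.
#'
#' @return A list with `standards` (concentration, absorbance), `samples`
#'   (sample, triplicate absorbances, dry_mass_mg) and `truth`.
#' @export
gen_assay_plate <- function(true_mass_fractions, dry_mass_mg,
                            digest_volume_uL = 200,
                            working_range = c(0, 4), n_standards = 8,
                            slope = 0.2, intercept = 0.05,
                            noise_sd = 0, seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  dry_mass_mg <- rep_len(dry_mass_mg, length(true_mass_fractions))
  conc_true <- true_mass_fractions * dry_mass_mg / digest_volume_uL
  if (any(conc_true < working_range[1L] | conc_true > working_range[2L])) {
    stop("true digest concentrations fall outside the working range")
  }
  std_conc <- seq(working_range[1L], working_range[2L], length.out = n_standards)
  std_abs <- slope * std_conc + intercept +
    if (noise_sd > 0) stats::rnorm(n_standards, 0, noise_sd) else 0
  samp <- lapply(seq_along(conc_true), function(i) {
    a <- slope * conc_true[i] + intercept +
      if (noise_sd > 0) stats::rnorm(3, 0, noise_sd) else rep(0, 3)
    data.frame(sample = names(true_mass_fractions)[i] %||% as.character(i),
               rep1 = a[1L], rep2 = a[2L], rep3 = a[3L],
               dry_mass_mg = dry_mass_mg[i])
  })
  list(
    standards = data.frame(concentration = std_conc, absorbance = std_abs),
    samples = do.call(rbind, samp),
    truth = data.frame(sample = names(true_mass_fractions) %||%
                         as.character(seq_along(conc_true)),
                       mass_fraction = true_mass_fractions,
                       digest_concentration = conc_true)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic immunohistochemistry image set
#'
#' Two-condition 12-bit intensity images with a horizontal scleral band, an
#' optic-nerve landmark column, Poisson-like noise, and configurable
#' enzyme/buffer intensity ratios (optionally different on the superior and
#' inferior side of the optic nerve).
#'
#' @param ratios List with `DS` and `C4S` true ratios; each either a scalar
#'   or `c(superior =, inferior =)`.
#' @param buffer_mean Mean buffer-only intensity inside the sclera. Default
#'   400 counts.
#' @param dim Image dimensions (rows, cols). Default `c(60, 120)`.
#' @param band_rows Row range of the scleral band.
#' @param noise Poisson-noise scaling (counts are drawn as
#'   `rpois(mean)` when TRUE); FALSE gives noiseless images.
#' @param seed Mandatory integer seed.
#'
#' @return A list as consumed by [normalized_fluorescence()], plus `truth`.
#' @export
gen_ihc_images <- function(ratios = list(DS = 3.69, C4S = 1.48),
                           buffer_mean = 400, dim = c(60L, 120L),
                           band_rows = 25:35, noise = TRUE, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (any(unlist(ratios) <= 0)) stop("ratios must be > 0")
  set.seed(seed)
  if (max(band_rows) > dim[1L]) stop("mask outside image")
  on_col <- as.integer(round(dim[2L] / 2))
  mask <- matrix(FALSE, dim[1L], dim[2L])
  mask[band_rows, ] <- TRUE
  mask[, on_col] <- FALSE # optic nerve excluded from the scleral mask
  side <- function(r) {
    r <- rep_len(unlist(r), 2L)
    m <- matrix(r[2L], dim[1L], dim[2L])
    m[, seq_len(on_col - 1L)] <- r[1L]
    m
  }
  render <- function(ratio_matrix) {
    mu <- matrix(buffer_mean * 0.1, dim[1L], dim[2L]) # dim background
    mu[mask] <- (buffer_mean * ratio_matrix)[mask]
    counts <- if (noise) matrix(stats::rpois(length(mu), mu), dim[1L]) else round(mu)
    matrix(pmin(as.integer(counts), 4095L), dim[1L])
  }
  list(
    ChB = render(side(ratios$DS)),
    ChAC = render(side(ratios$C4S)),
    buffer = render(matrix(1, dim[1L], dim[2L])),
    mask = mask,
    optic_nerve_col = on_col,
    truth = ratios
  )
}
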