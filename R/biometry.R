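# Ocular biometry from delineated OCT interface positions, plus the two
# longitudinal statistics used throughout: "shift" (value relative to the
# control-group mean at the same timepoint) and "delta" (within-animal
# change from baseline). Animals are represented in a long-format table:
# animal_id, eye, treatment, timepoint, age_days, outcome, value, excluded,
# reason.

#' Convert optical path length to geometric distance
#'
#' OCT measures optical path; geometric distance is obtained by dividing by
#' the average ocular refractive index (default 1.39).
#'
#' @param optical_path Optical path length(s), um (>= 0).
#' @param refractive_index Average refractive index (> 0). Default 1.39.
#' @return Geometric distance(s), um.
#' @examples
#' optical_to_geometric(1390) # 1000
#' @export
optical_to_geometric <- function(optical_path, refractive_index = 1.39) {
  if (!is.numeric(refractive_index) || refractive_index <= 0) {
    stop("refractive_index must be > 0")
  }
  if (any(optical_path < 0)) stop("optical_path must be >= 0")
  optical_path / refractive_index
}

#' Derive axial biometry from interface positions
#'
#' Converts the six delineated A-scan interface positions (anterior cornea,
#' posterior cornea, anterior lens, posterior lens, vitreoretinal interface,
#' RPE; optical um, strictly increasing) into segment thicknesses and axial
#' length: CCT, ACD, LT, VCD, RT and AL (anterior corneal surface to RPE).
#' By construction AL equals the sum of the five segments.
#'
#' @param interfaces Numeric vector of 6 optical positions (um), in order.
#' @param refraction Refractive error, diopters (passed through).
#' @param refractive_index Average refractive index. Default 1.39.
#' @param animal_id,eye,timepoint,age_days Metadata passed through.
#'
#' @return A one-row data frame with the metadata, `CCT`, `ACD`, `LT`,
#'   `VCD`, `RT`, `AL` (geometric um) and `RE` (D).
#' @export
derive_biometry <- function(interfaces, refraction = NA_real_,
                            refractive_index = 1.39,
                            animal_id = NA_character_, eye = NA_character_,
                            timepoint = NA_character_, age_days = NA_real_) {
  if (length(interfaces) != 6L) stop("need exactly 6 interface positions")
  if (any(diff(interfaces) <= 0)) {
    bad <- which(diff(interfaces) <= 0)[1L]
    stop(sprintf("interfaces must be strictly increasing (positions %d and %d are not)",
                 bad, bad + 1L))
  }
  geo <- optical_to_geometric(interfaces, refractive_index)
  seg <- diff(geo)
  data.frame(
    animal_id = animal_id, eye = eye, timepoint = timepoint,
    age_days = age_days,
    CCT = seg[1L], ACD = seg[2L], LT = seg[3L], VCD = seg[4L], RT = seg[5L],
    AL = geo[6L] - geo[1L], RE = refraction
  )
}

# Eye-averaged per-animal values of one outcome at one timepoint.
eye_average <- function(data, outcome, timepoint = NULL) {
  excl <- if (is.null(data$excluded)) rep(FALSE, nrow(data)) else isTRUE_col(data$excluded)
  d <- data[data$outcome == outcome & !excl, , drop = FALSE]
  if (!is.null(timepoint)) d <- d[d$timepoint == timepoint, , drop = FALSE]
  if (!nrow(d)) return(d[, c("animal_id", "treatment", "timepoint", "value")])
  agg <- stats::aggregate(value ~ animal_id + treatment + timepoint, data = d,
                          FUN = mean)
  agg[order(agg$timepoint, agg$animal_id), , drop = FALSE]
}

isTRUE_col <- function(x) {
  if (is.null(x)) rep(FALSE, 0L) else !is.na(x) & as.logical(x)
}

check_cohort_table <- function(data) {
  need <- c("animal_id", "treatment", "timepoint", "outcome", "value")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("cohort table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"excluded" %in% names(data)) data$excluded <- FALSE
  data
}

#' Shift statistic: value relative to the control-group mean
#'
#' For each animal at a timepoint, the shift is the animal's eye-averaged
#' value minus the mean of the control group at that timepoint. The mean
#' shift of the control group is therefore zero by construction.
#'
#' @param data Long-format cohort table (see module description).
#' @param outcome Outcome name, e.g. `"VCD"`.
#' @param timepoint Timepoint label, e.g. `"t2wk"`.
#' @param control Treatment label of the reference group. Default `"Ctrl"`.
#'
#' @return A list with `per_animal` (animal_id, treatment, shift) and
#'   `summary` (per-treatment mean, SD, n).
#' @export
shift_statistic <- function(data, outcome, timepoint, control = "Ctrl") {
  data <- check_cohort_table(data)
  avg <- eye_average(data, outcome, timepoint)
  if (!nrow(avg)) stop(sprintf("no data for outcome %s at timepoint %s", outcome, timepoint))
  ctrl <- avg$value[avg$treatment == control]
  if (!length(ctrl)) stop("control group empty at this timepoint")
  per <- data.frame(
    animal_id = avg$animal_id, treatment = avg$treatment,
    timepoint = timepoint, outcome = outcome,
    shift = avg$value - mean(ctrl)
  )
  summ <- do.call(rbind, lapply(split(per, per$treatment), function(d) {
    data.frame(treatment = d$treatment[1L], mean = mean(d$shift),
               sd = stats::sd(d$shift), n = nrow(d))
  }))
  rownames(summ) <- NULL
  list(per_animal = per, summary = summ)
}

#' Change-from-baseline statistic
#'
#' For each animal, the eye-averaged value at each timepoint minus the
#' animal's own eye-averaged baseline value. Delta at baseline is exactly
#' zero; animals lacking a baseline are excluded with a logged reason.
#'
#' @inheritParams shift_statistic
#' @param baseline Baseline timepoint label. Default `"t0"`.
#'
#' @return A list with `per_animal` (animal_id, treatment, timepoint,
#'   delta), `summary` (per treatment x timepoint mean, SD, n) and
#'   `dropped` (animal ids without baseline).
#' @export
delta_from_baseline <- function(data, outcome, baseline = "t0") {
  data <- check_cohort_table(data)
  avg <- eye_average(data, outcome)
  base <- avg[avg$timepoint == baseline, c("animal_id", "value")]
  names(base)[2L] <- "baseline"
  merged <- merge(avg, base, by = "animal_id")
  dropped <- setdiff(unique(avg$animal_id), base$animal_id)
  per <- data.frame(
    animal_id = merged$animal_id, treatment = merged$treatment,
    timepoint = merged$timepoint, outcome = outcome,
    delta = merged$value - merged$baseline
  )
  summ <- do.call(rbind, lapply(
    split(per, list(per$treatment, per$timepoint), drop = TRUE),
    function(d) data.frame(treatment = d$treatment[1L],
                           timepoint = d$timepoint[1L],
                           mean = mean(d$delta), sd = stats::sd(d$delta),
                           n = nrow(d))
  ))
  rownames(summ) <- NULL
  list(per_animal = per, summary = summ, dropped = dropped)
}

#' Apply opacity-based eye exclusions
#'
#' Removes eyes flagged with opacities from analysis; the animal is retained
#' with its remaining eye. Returns the filtered table and an audit log.
#'
#' @param data Long-format cohort table with `excluded` and `reason`.
#'
#' @return A list with `data` (rows with excluded eyes removed) and `audit`
#'   (counts: eyes flagged, animals fully dropped).
#' @export
apply_exclusions <- function(data) {
  data <- check_cohort_table(data)
  excl <- isTRUE_col(data$excluded)
  flagged <- unique(data[excl, c("animal_id", "eye"), drop = FALSE])
  kept <- data[!excl, , drop = FALSE]
  dropped_animals <- setdiff(unique(data$animal_id), unique(kept$animal_id))
  list(
    data = kept,
    audit = list(
      eyes_flagged = nrow(flagged),
      animals_dropped = length(dropped_animals),
      dropped_ids = dropped_animals,
      reasons = table(data$reason[excl])
    )
  )
}

#' Dose arithmetic for medicated pellets
#'
#' Converts a pellet feeding rate (mg pellet per g body mass) and the drug
#' mass fraction of the pellet into a dose in mg drug per kg body mass.
#'
#' @param pellet_rate mg pellet per g body mass (>= 0).
#' @param mass_fraction Drug mass fraction of the pellet, in (0, 1].
#' @return Dose in mg/kg.
#' @examples
#' dose_from_pellet(2.5, 0.01) # 25 mg/kg
#' @export
dose_from_pellet <- function(pellet_rate, mass_fraction) {
  if (any(pellet_rate < 0)) stop("pellet_rate must be >= 0")
  if (any(mass_fraction <= 0 | mass_fraction > 1)) {
    stop("mass_fraction must be in (0, 1]")
  }
  pellet_rate * mass_fraction * 1000
}
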