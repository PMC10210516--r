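# Biochemical quantification arithmetic: DMMB (sulfated GAG) and PicoGreen
# (DNA) standard curves with inverse prediction and mass normalization, and
# immunohistochemistry normalized-fluorescence ratios with a regional
# (superior/inferior) split at the optic nerve.

#' Fit a linear standard curve
#'
#' Ordinary least-squares straight line `absorbance ~ concentration` through
#' the measured standards. Inverse prediction is defined on the working
#' range spanned by the standards; values outside it are flagged as
#' extrapolations.
#'
#' @param concentrations Standard concentrations (assay units), >= 2
#'   distinct values; the zero-concentration standard serves as the blank.
#' @param absorbances Measured absorbances, same length.
#' @param analyte Label, e.g. `"sGAG"` or `"DNA"`.
#' @param lof_tol Maximum tolerated lack of fit, expressed as residual SD
#'   relative to the fitted absorbance span, before the curve is rejected as
#'   non-linear/non-monotone. Default 0.05.
#'
#' @return An object of class `standard_curve`: slope, intercept, R2,
#'   working range, analyte.
#' @export
fit_standard_curve <- function(concentrations, absorbances, analyte = "analyte",
                               lof_tol = 0.05) {
  stopifnot(length(concentrations) == length(absorbances))
  if (length(unique(concentrations)) < 2L) stop("need >= 2 distinct concentrations")
  fit <- stats::lm(absorbances ~ concentrations)
  slope <- stats::coef(fit)[[2L]]
  intercept <- stats::coef(fit)[[1L]]
  span <- abs(slope) * diff(range(concentrations))
  if (span <= 1e-6 * max(abs(absorbances), 1)) {
    stop("standards have no response (flat or negligible slope)")
  }
  lof <- sqrt(mean(stats::residuals(fit)^2)) / span
  if (slope <= 0 || lof > lof_tol) {
    stop("standards are non-monotone or depart from a line beyond tolerance")
  }
  r2 <- stats::cor(absorbances, stats::fitted(fit))^2
  structure(list(
    analyte = analyte, slope = slope, intercept = intercept, r_squared = r2,
    working_range = range(concentrations),
    concentrations = concentrations, absorbances = absorbances
  ), class = "standard_curve")
}

#' Inverse-predict concentration from absorbance
#'
#' @param curve A [fit_standard_curve()] object.
#' @param absorbance Absorbance value(s) (blank-subtracted absorbances are
#'   expected when `blank` is 0).
#' @param blank Blank absorbance subtracted before inversion. Default 0.
#' @return A data frame with `concentration` and logical `extrapolated`.
#' @export
inverse_predict <- function(curve, absorbance, blank = 0) {
  stopifnot(inherits(curve, "standard_curve"))
  conc <- (absorbance - blank - curve$intercept) / curve$slope
  data.frame(
    concentration = conc,
    extrapolated = conc < curve$working_range[1L] | conc > curve$working_range[2L]
  )
}

#' Quantify an analyte in a digested tissue sample
#'
#' Triplicate absorbances are averaged, blank-subtracted, and converted to a
#' digest concentration by inverse prediction on the standard curve; the
#' total analyte is `concentration x digest volume` (the concentration is
#' intensive, so splitting the digestate between assays does not change it),
#' and the mass fraction is total analyte over scleral dry mass.
#'
#' @param absorbances Triplicate absorbances of the sample.
#' @param curve A [fit_standard_curve()] object.
#' @param dry_mass_mg Scleral dry mass, mg (mean of three weighings).
#' @param digest_volume_uL Papain digest volume, uL. Default 200.
#' @param blank Blank absorbance (the 0-concentration standard's
#'   absorbance, i.e. the curve intercept by default).
#'
#' @return A list: `concentration` (assay units, per uL), `total_ug`,
#'   `mass_fraction_ug_per_mg`, `below_blank` flag, `extrapolated` flag.
#' @export
quantify_sample <- function(absorbances, curve, dry_mass_mg,
                            digest_volume_uL = 200, blank = curve$intercept) {
  stopifnot(inherits(curve, "standard_curve"))
  if (dry_mass_mg <= 0) stop("dry_mass_mg must be > 0")
  mean_abs <- mean(absorbances)
  below <- mean_abs < blank
  inv <- inverse_predict(curve, max(mean_abs, blank), blank = blank - curve$intercept)
  conc <- if (below) 0 else inv$concentration
  total <- conc * digest_volume_uL
  list(
    concentration = conc,
    total_ug = total,
    mass_fraction_ug_per_mg = total / dry_mass_mg,
    below_blank = below,
    extrapolated = !below && inv$extrapolated
  )
}

#' GAG/DNA mass ratio for one sample
#'
#' Per-eye ratio of the two mass fractions (ug sGAG per ug DNA).
#'
#' @param gag,dna Outputs of [quantify_sample()] for the same eye.
#' @return Ratio in ug/ug.
#' @export
gag_dna_ratio <- function(gag, dna) {
  if (dna$mass_fraction_ug_per_mg <= 0) stop("DNA mass fraction must be > 0")
  gag$mass_fraction_ug_per_mg / dna$mass_fraction_ug_per_mg
}

#' Normalized fluorescence of chondroitinase-treated sections
#'
#' Ratio of masked mean pixel intensities of an enzyme-treated section to
#' the buffer-only section from the same eye: `DS` uses the chondroitinase-B
#' image, `C4S` the chondroitinase-AC image. The regional variant restricts
#' the mask to one side of the optic nerve.
#'
#' @param images A list with integer intensity matrices `ChB`, `ChAC`,
#'   `buffer` (12-bit, 0-4095), a logical `mask` matrix, and
#'   `optic_nerve_col` (column index of the optic-nerve landmark).
#' @param region `"whole"`, `"superior"` (columns left of the optic nerve)
#'   or `"inferior"` (right).
#'
#' @return A list with `DS`, `C4S` ratios and the `saturation_fraction` of
#'   each channel.
#' @export
normalized_fluorescence <- function(images, region = c("whole", "superior", "inferior")) {
  region <- match.arg(region)
  need <- c("ChB", "ChAC", "buffer", "mask")
  if (!all(need %in% names(images))) {
    stop("images must contain ", paste(need, collapse = ", "))
  }
  mask <- images$mask
  for (nm in c("ChB", "ChAC", "buffer")) {
    if (!all(dim(images[[nm]]) == dim(mask))) stop("mask and images differ in size")
  }
  if (region != "whole") {
    split_col <- images$optic_nerve_col
    if (is.null(split_col)) stop("regional analysis needs optic_nerve_col")
    cols <- col(mask)
    mask <- mask & if (region == "superior") cols < split_col else cols > split_col
  }
  if (!any(mask)) stop("empty mask for region ", region)
  mmean <- function(img) mean(img[mask])
  buf <- mmean(images$buffer)
  if (buf <= 0) stop("buffer-only mean intensity must be > 0")
  sat <- function(img) mean(img[mask] >= 4095)
  list(
    DS = mmean(images$ChB) / buf,
    C4S = mmean(images$ChAC) / buf,
    saturation_fraction = c(ChB = sat(images$ChB), ChAC = sat(images$ChAC),
                            buffer = sat(images$buffer))
  )
}
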