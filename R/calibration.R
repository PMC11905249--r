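# CT-number <-> iodine concentration calibration and CT-number -> material
# conversion (media map + density ramp).

#' Linear HU-to-concentration calibration through two anchor points
#'
#' Constructs the conversion line between CT number (HU) and iodinated
#' agent concentration (mg/mL) passing exactly through two measured anchor
#' points.
#'
#' @param anchor_low,anchor_high numeric length-2 vectors `c(hu, conc)`;
#'   concentrations in mg/mL, nonnegative and distinct
#' @return an object of class `hu_calibration` with fields `slope`
#'   (HU per mg/mL), `intercept` (HU at zero concentration) and
#'   `valid_range` (mg/mL interval spanned by the anchors)
#' @export
calibration_from_anchors <- function(anchor_low, anchor_high) {
  hu <- c(anchor_low[1], anchor_high[1])
  cc <- c(anchor_low[2], anchor_high[2])
  if (any(cc < 0)) {
    abort("anchor concentrations must be nonnegative",
          class = "kvcert_calibration_error")
  }
  if (hu[1] == hu[2] || cc[1] == cc[2]) {
    abort("anchors must have distinct HU and distinct concentrations",
          class = "kvcert_degenerate_curve_error")
  }
  slope <- (hu[2] - hu[1]) / (cc[2] - cc[1])
  if (slope <= 0) {
    abort("CT number must increase with concentration (slope > 0)",
          class = "kvcert_calibration_error")
  }
  structure(
    list(slope = slope, intercept = hu[1] - slope * cc[1],
         valid_range = range(cc), anchors = cbind(hu = hu, conc = cc)),
    class = "hu_calibration")
}

#' Default Lipiodol calibration
#'
#' The line through the clinical extreme anchors (376.2 HU, 11.4 mg/mL) and
#' (1653 HU, 49.4 mg/mL) measured at 120 kVp.
#'
#' @return an `hu_calibration` object
#' @export
lipiodol_calibration <- function() {
  calibration_from_anchors(c(376.2, 11.4), c(1653, 49.4))
}

#' @export
print.hu_calibration <- function(x, ...) {
  cat(sprintf("<HU calibration: HU = %.4g * c + %.4g, valid %g-%g mg/mL>\n",
              x$slope, x$intercept, x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

#' @rdname calibration_from_anchors
#' @param x an `hu_calibration` object
#' @param ... unused
#' @method tidy hu_calibration
#' @export
tidy.hu_calibration <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         unit = c("HU", "HU per mg/mL"))
}

#' @rdname calibration_from_anchors
#' @method glance hu_calibration
#' @export
glance.hu_calibration <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         conc_min = x$valid_range[1], conc_max = x$valid_range[2])
}

#' Convert between CT number and concentration
#'
#' Exact inverses of each other on the calibration line. Values outside the
#' calibrated concentration interval are extrapolated with a warning.
#'
#' @param curve an [calibration_from_anchors()] object
#' @param hu CT numbers (HU)
#' @param concentration concentrations (mg/mL)
#' @return numeric vector (mg/mL or HU)
#' @export
hu_to_concentration <- function(curve, hu) {
  stopifnot(inherits(curve, "hu_calibration"))
  conc <- (hu - curve$intercept) / curve$slope
  tol <- 1e-9 * diff(curve$valid_range)
  out_of_range <- conc < curve$valid_range[1] - tol |
    conc > curve$valid_range[2] + tol
  if (any(out_of_range)) {
    warn(sprintf("%d value(s) extrapolated outside the calibrated range %g-%g mg/mL",
                 sum(out_of_range), curve$valid_range[1], curve$valid_range[2]),
         class = "kvcert_extrapolation_warning")
  }
  conc
}

#' @rdname hu_to_concentration
#' @export
concentration_to_hu <- function(curve, concentration) {
  stopifnot(inherits(curve, "hu_calibration"))
  tol <- 1e-9 * diff(curve$valid_range)
  out_of_range <- concentration < curve$valid_range[1] - tol |
    concentration > curve$valid_range[2] + tol
  if (any(out_of_range)) {
    warn(sprintf("%d value(s) extrapolated outside the calibrated range %g-%g mg/mL",
                 sum(out_of_range), curve$valid_range[1], curve$valid_range[2]),
         class = "kvcert_extrapolation_warning")
  }
  curve$intercept + curve$slope * concentration
}

#' Iodinated (Lipiodol-like) tumour filling material
#'
#' Models the embolised tumour medium as iodine dispersed in soft tissue
#' with volume-additive density: \eqn{\rho(c) = \rho_{base} + c/1000} g/cm^3
#' and iodine mass fraction \eqn{w_I = (c/1000) / \rho(c)} for concentration
#' `c` in mg/mL. At `c = 0` the base medium is returned unchanged.
#'
#' @param concentration iodine-bearing agent concentration, mg/mL, in
#'   `[0, 480]`
#' @param base base medium, a material name or [material_composition()]
#'   (default soft tissue)
#' @param calibration calibration used to attach the expected CT number
#' @return a [material_composition()] with attributes `concentration`
#'   (mg/mL) and `hu_value` (HU from the calibration line)
#' @export
lipiodol_material <- function(concentration,
                              base = standard_material("soft_tissue"),
                              calibration = lipiodol_calibration()) {
  if (!is.finite(concentration) || concentration < 0 || concentration > 480) {
    abort("concentration must lie in [0, 480] mg/mL",
          class = "kvcert_domain_error")
  }
  base <- as_material(base)
  rho <- base$density + concentration / 1000
  w_i <- (concentration / 1000) / rho
  elements <- c(base$elements * (1 - w_i))
  if (w_i > 0) {
    elements["I"] <- (if (!is.na(elements["I"])) elements[["I"]] else 0) + w_i
    elements <- elements[elements > 0]
  }
  m <- material_composition(
    if (concentration > 0) sprintf("lipiodol_%gmgml", concentration)
    else base$name,
    elements, rho)
  hu <- suppressWarnings(concentration_to_hu(calibration, concentration))
  attr(m, "concentration") <- concentration
  attr(m, "hu_value") <- hu
  m
}

#' Default HU banding for the media map
#'
#' Conventional CT-calibration thresholds splitting the HU axis into air,
#' lung, soft tissue and bone, with the piecewise-linear HU-to-density ramp
#' used within each band.
#'
#' @return a list with `thresholds` (air/lung, lung/soft, soft/bone HU) and
#'   ramp anchor points
#' @export
hu_band_defaults <- function() {
  list(thresholds = c(air_lung = -850, lung_soft = -200, soft_bone = 120),
       # density ramp anchors: HU -> g/cm^3, interpolated linearly per band
       ramp = data.frame(
         hu = c(-1000, -850, -200, 0, 120, 1500, 3000),
         density = c(0.0012048, 0.15, 0.80, 1.00, 1.12, 1.92, 2.8)))
}

#' Convert CT numbers to the media map and mass density
#'
#' Piecewise assignment of each HU value to one of air, lung, soft tissue
#' or bone, with a continuous HU-to-density ramp.
#'
#' @param hu CT numbers (HU), finite
#' @param bands banding configuration, see [hu_band_defaults()]
#' @return a tibble with columns `hu`, `material`, `density`
#' @export
hu_to_material <- function(hu, bands = hu_band_defaults()) {
  if (any(!is.finite(hu))) {
    abort("hu must be finite", class = "kvcert_domain_error")
  }
  th <- bands$thresholds
  material <- ifelse(hu < th[["air_lung"]], "air",
              ifelse(hu < th[["lung_soft"]], "lung",
              ifelse(hu <= th[["soft_bone"]], "soft_tissue",
                     "cortical_bone")))
  density <- approx(bands$ramp$hu, bands$ramp$density, xout = hu,
                    rule = 2)$y
  density <- pmax(density, 0.0012048)
  tibble(hu = hu, material = material, density = density)
}
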