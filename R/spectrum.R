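# Filtered 120 kVp CT-scanner beam model: semi-empirical tungsten-anode
# spectrum, titanium inherent filtration calibrated to a target HVL,
# Teflon bowtie geometry, off-center ratio, and source-photon sampling.

W_LINES_KEV <- c(57.98, 59.32, 67.24, 69.07)   # W K-alpha2/alpha1/beta1/beta2
W_LINES_REL <- c(0.58, 1.00, 0.33, 0.09)

#' Teflon bowtie filter profile
#'
#' Thickness as a function of fan angle: quadratic in angle, even-symmetric,
#' running from `center_cm` on the central axis to `edge_cm` at the edge of
#' the fan.
#'
#' @param center_cm thickness on the central axis (cm)
#' @param edge_cm thickness at the fan edge (cm)
#' @param fan_half_angle_deg half fan angle covered by the profile
#' @return a `bowtie_filter` object
#' @export
bowtie_filter <- function(center_cm = 0.15, edge_cm = 2.8,
                          fan_half_angle_deg = 22) {
  stopifnot(center_cm > 0, edge_cm >= center_cm, fan_half_angle_deg > 0)
  structure(list(center_cm = center_cm, edge_cm = edge_cm,
                 fan_half_angle_rad = fan_half_angle_deg * pi / 180),
            class = "bowtie_filter")
}

#' @rdname bowtie_filter
#' @param bowtie a `bowtie_filter`
#' @param angle_rad fan angle(s) in radians
#' @return thickness in cm at each angle
#' @export
bowtie_thickness <- function(bowtie, angle_rad) {
  u <- pmin(abs(angle_rad) / bowtie$fan_half_angle_rad, 1)
  bowtie$center_cm + (bowtie$edge_cm - bowtie$center_cm) * u^2
}

#' CT scanner source geometry
#'
#' @param focal_to_axis_cm focal spot to rotation axis distance (cm)
#' @param inherent_ti_cm titanium inherent filter thickness (cm); calibrate
#'   with [calibrate_inherent_filtration()]
#' @param bowtie a [bowtie_filter()]
#' @param field_cm rectangular aperture (width, height) at the isocenter
#'   plane, cm
#' @return a `scanner_geometry` object
#' @export
scanner_geometry <- function(focal_to_axis_cm = 62.56,
                             inherent_ti_cm = 0.3,
                             bowtie = bowtie_filter(),
                             field_cm = c(4, 4)) {
  stopifnot(focal_to_axis_cm > 0, all(field_cm > 0))
  structure(list(focal_to_axis_cm = focal_to_axis_cm,
                 inherent_ti_cm = inherent_ti_cm,
                 bowtie = bowtie, field_cm = field_cm),
            class = "scanner_geometry")
}

#' Generate the filtered tube spectrum
#'
#' Semi-empirical tungsten-anode model: Kramers bremsstrahlung photon
#' fluence \eqn{\phi(E) \propto (E_{max}-E)/E} plus the tungsten K
#' characteristic lines, attenuated through the titanium inherent filter
#' and normalised to unit total fluence. 1 keV bins from 5 keV to the tube
#' potential.
#'
#' @param kvp tube potential in kV (40-150)
#' @param inherent_ti_cm titanium filtration (cm)
#' @param characteristic_fraction fraction of unfiltered fluence in the K
#'   lines
#' @return an `xray_spectrum` tibble with columns `energy_keV` (bin centre)
#'   and `fluence` (normalised), and attributes `kvp`, `bin_edges`,
#'   `inherent_ti_cm`
#' @export
generate_spectrum <- function(kvp = 120, inherent_ti_cm = 0.3,
                              characteristic_fraction = 0.08) {
  if (!is.finite(kvp) || kvp < 40 || kvp > 150) {
    abort("kvp must lie in [40, 150]", class = "kvcert_domain_error")
  }
  edges <- seq(5, kvp, by = 1)
  centers <- head(edges, -1) + diff(edges) / 2
  brems <- pmax(kvp - centers, 0) / centers
  brems <- brems / sum(brems)
  fluence <- brems
  lines_in <- W_LINES_KEV < kvp
  if (any(lines_in) && characteristic_fraction > 0) {
    w <- W_LINES_REL[lines_in] / sum(W_LINES_REL[lines_in]) *
      characteristic_fraction
    idx <- findInterval(W_LINES_KEV[lines_in], edges)
    fluence <- fluence * (1 - characteristic_fraction)
    for (k in seq_along(idx)) {
      fluence[idx[k]] <- fluence[idx[k]] + w[k]
    }
  }
  if (inherent_ti_cm > 0) {
    mu_ti <- mixture_mu("titanium", centers, "total") * 4.506
    fluence <- fluence * exp(-mu_ti * inherent_ti_cm)
  }
  out <- tibble(energy_keV = centers, fluence = fluence / sum(fluence))
  structure(out, class = c("xray_spectrum", class(out)),
            kvp = kvp, bin_edges = edges, inherent_ti_cm = inherent_ti_cm)
}

#' @method autoplot xray_spectrum
#' @export
autoplot.xray_spectrum <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$energy_keV, y = .data$fluence)) +
    geom_step() +
    labs(x = "energy (keV)", y = "relative fluence",
         title = sprintf("%g kVp filtered spectrum", attr(object, "kvp"))) +
    theme_minimal()
}

# air-kerma weighted transmission of a spectrum through t mm of Al
spectrum_transmission_al <- function(spectrum, t_mm) {
  E <- spectrum$energy_keV
  w <- spectrum$fluence * E * mixture_mu("air", E, "mu_en")
  mu <- mixture_mu("aluminum", E, "total") * ALUMINUM_DENSITY
  vapply(t_mm, function(t) sum(w * exp(-mu * t / 10)) / sum(w), numeric(1))
}

#' Aluminum HVL of a spectrum
#'
#' Solves the air-kerma weighted narrow-beam transmission
#' \eqn{T(t) = \sum \phi E (\mu_{en}/\rho)_{air} e^{-\mu_{Al} t} / \sum
#' \phi E (\mu_{en}/\rho)_{air} = 1/2} by bisection (an ionization-chamber
#' surrogate for the measured HVL).
#'
#' @param spectrum an [generate_spectrum()] result (normalised fluence)
#' @return first HVL in mm of aluminum
#' @export
hvl_of_spectrum <- function(spectrum) {
  lo <- 0; hi <- 40
  if (spectrum_transmission_al(spectrum, hi) > 0.5) {
    abort("transmission does not reach 0.5 within 40 mm Al",
          class = "kvcert_numeric_error")
  }
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (spectrum_transmission_al(spectrum, mid) > 0.5) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Calibrate the titanium inherent filtration to a target beam quality
#'
#' Bisection on the titanium thickness until the spectrum's aluminum HVL
#' matches `target_hvl_mm` within `tol_mm`.
#'
#' @param target_hvl_mm target first HVL (mm Al)
#' @param kvp tube potential (kV)
#' @param bounds_cm titanium thickness search interval (cm)
#' @param tol_mm HVL tolerance (mm)
#' @return a list with `ti_cm`, `achieved_hvl_mm` and the calibrated
#'   `spectrum`
#' @export
calibrate_inherent_filtration <- function(target_hvl_mm = 9.4, kvp = 120,
                                          bounds_cm = c(0.05, 2),
                                          tol_mm = 0.05) {
  h <- function(t) hvl_of_spectrum(generate_spectrum(kvp, t))
  lo <- bounds_cm[1]; hi <- bounds_cm[2]
  h_lo <- h(lo); h_hi <- h(hi)
  if (target_hvl_mm < h_lo || target_hvl_mm > h_hi) {
    abort(sprintf(
      "target HVL %.2f mm not bracketed: Ti %g cm gives %.2f mm, %g cm gives %.2f mm",
      target_hvl_mm, lo, h_lo, hi, h_hi),
      class = "kvcert_calibration_error")
  }
  repeat {
    mid <- (lo + hi) / 2
    h_mid <- h(mid)
    if (abs(h_mid - target_hvl_mm) < tol_mm || (hi - lo) < 1e-5) break
    if (h_mid < target_hvl_mm) lo <- mid else hi <- mid
  }
  list(ti_cm = mid, achieved_hvl_mm = h_mid,
       spectrum = generate_spectrum(kvp, mid))
}

#' Off-center ratio at the isocenter plane
#'
#' Air kerma versus lateral offset, each ray attenuated by the bowtie
#' thickness at its fan angle and by the inverse-square distance, normalised
#' to the central axis.
#'
#' @param geometry a [scanner_geometry()]
#' @param offsets_cm lateral offsets at the isocenter plane (cm)
#' @param spectrum spectrum incident on the bowtie (default: spectrum from
#'   the geometry's inherent filtration)
#' @return a tibble with `offset_cm` and `ocr`
#' @export
off_center_ratio <- function(geometry, offsets_cm,
                             spectrum = generate_spectrum(
                               120, geometry$inherent_ti_cm)) {
  ftd <- geometry$focal_to_axis_cm
  ang <- atan(offsets_cm / ftd)
  if (any(abs(ang) > geometry$bowtie$fan_half_angle_rad)) {
    abort("offset outside the fan coverage", class = "kvcert_coverage_error")
  }
  E <- spectrum$energy_keV
  w <- spectrum$fluence * E * mixture_mu("air", E, "mu_en")
  mu_tef <- mixture_mu("teflon", E, "total") * 2.2
  kerma <- vapply(seq_along(ang), function(i) {
    path <- bowtie_thickness(geometry$bowtie, ang[i]) / cos(ang[i])
    invsq <- ftd^2 / (ftd^2 + offsets_cm[i]^2)
    sum(w * exp(-mu_tef * path)) * invsq
  }, numeric(1))
  path0 <- bowtie_thickness(geometry$bowtie, 0)
  kerma0 <- sum(w * exp(-mu_tef * path0))
  out <- tibble(offset_cm = offsets_cm, ocr = kerma / kerma0)
  structure(out, class = c("ocr_profile", class(out)))
}

#' @method autoplot ocr_profile
#' @export
autoplot.ocr_profile <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$offset_cm, y = .data$ocr)) +
    geom_line() + geom_point() +
    labs(x = "lateral offset (cm)", y = "off-center ratio") +
    theme_minimal()
}

# spectrum after the bowtie at a given fan angle (internal; used by the
# source sampler and the transport wrappers)
spectrum_at_angle <- function(spectrum, bowtie, angle_rad) {
  E <- spectrum$energy_keV
  path <- bowtie_thickness(bowtie, angle_rad) / cos(angle_rad)
  mu_tef <- mixture_mu("teflon", E, "total") * 2.2
  f <- spectrum$fluence * exp(-mu_tef * path)
  f / sum(f)
}

#' Sample source photons
#'
#' Photons originate at the focal spot; directions are sampled uniformly
#' over the rectangular aperture projected to the isocenter plane; energies
#' are drawn by inverse-CDF sampling from the bowtie-filtered spectrum at
#' each photon's fan angle. Statistical weight is 1.
#'
#' @param n number of photons
#' @param geometry a [scanner_geometry()]
#' @param spectrum pre-bowtie spectrum
#' @param seed RNG seed
#' @param n_angle_bins number of fan-angle bins for the per-angle spectra
#' @return a tibble with focal-spot position, direction cosines, energy
#'   (keV) and weight
#' @export
sample_source_photon <- function(n, geometry, spectrum, seed = 1,
                                 n_angle_bins = 32) {
  set.seed(seed)
  ftd <- geometry$focal_to_axis_cm
  half <- geometry$field_cm / 2
  # aperture points at the isocenter plane; focal spot at (0, -ftd, 0),
  # beam along +y
  ax <- runif(n, -half[1], half[1])
  az <- runif(n, -half[2], half[2])
  dirs <- cbind(ax, ftd, az)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  fan <- atan(ax / ftd)
  # bin fan angles, sample energy from the binned filtered spectrum
  max_ang <- max(abs(fan)) + 1e-12
  bins <- pmin(floor(abs(fan) / max_ang * n_angle_bins) + 1L, n_angle_bins)
  centers_ang <- (seq_len(n_angle_bins) - 0.5) / n_angle_bins * max_ang
  E <- spectrum$energy_keV
  edges <- attr(spectrum, "bin_edges")
  energy <- numeric(n)
  for (b in unique(bins)) {
    f <- spectrum_at_angle(spectrum, geometry$bowtie, centers_ang[b])
    idx <- which(bins == b)
    u <- runif(length(idx))
    cdf <- cumsum(f)
    k <- findInterval(u, c(0, cdf), rightmost.closed = TRUE)
    k <- pmin(pmax(k, 1L), length(E))
    # uniform within the 1 keV bin
    energy[idx] <- edges[k] + runif(length(idx)) * (edges[k + 1] - edges[k])
  }
  tibble(x = 0, y = -ftd, z = 0,
         ux = dirs[, 1], uy = dirs[, 2], uz = dirs[, 3],
         energy_keV = energy, weight = 1)
}

#' Write / read a spectrum as two-column TSV
#'
#' @param spectrum an `xray_spectrum`
#' @param path file path
#' @return `read_spectrum` returns an `xray_spectrum` tibble (kvp inferred
#'   from the highest bin edge)
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.table(
    data.frame(energy_keV = spectrum$energy_keV,
               relative_fluence = spectrum$fluence),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  d <- read.delim(path)
  kvp <- max(d$energy_keV) + 0.5
  out <- tibble(energy_keV = d$energy_keV,
                fluence = d$relative_fluence / sum(d$relative_fluence))
  structure(out, class = c("xray_spectrum", class(out)), kvp = kvp,
            bin_edges = c(d$energy_keV - 0.5, kvp), inherent_ti_cm = NA_real_)
}
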