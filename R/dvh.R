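# Dose-volume histograms and scalar plan metrics.
#
# Conventions (documented in the methods vignette): voxel-centre dose with
# equal voxel volumes; Dx% by midpoint-interpolated percentile of the
# descending dose distribution (ties toward the higher dose); Dxcc by
# discrete accumulation of voxel volumes in descending dose order; VxGy as
# percent of structure volume.

#' Cumulative dose-volume histogram
#'
#' Volume-weighted cumulative histogram over the masked voxels: fraction of
#' the structure volume receiving at least each dose level.
#'
#' @param dose 3D dose array (Gy)
#' @param mask logical mask (same shape), nonempty
#' @param bin_gy histogram bin width (Gy)
#' @return a `dvh_curve` tibble with `dose_gy` (bin lower edges, starting
#'   at 0) and `volume_fraction`
#' @export
cumulative_dvh <- function(dose, mask, bin_gy = 0.05) {
  if (!any(mask)) {
    abort("empty structure mask", class = "kvcert_structure_error")
  }
  if (bin_gy <= 0) {
    abort("bin width must be positive", class = "kvcert_domain_error")
  }
  d <- dose[mask]
  edges <- seq(0, max(d) + bin_gy, by = bin_gy)
  vf <- vapply(edges, function(e) mean(d >= e), numeric(1))
  out <- tibble(dose_gy = edges, volume_fraction = vf)
  structure(out, class = c("dvh_curve", class(out)))
}

#' @method autoplot dvh_curve
#' @export
autoplot.dvh_curve <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$dose_gy,
                                y = 100 * .data$volume_fraction)) +
    geom_step() +
    labs(x = "dose (Gy)", y = "volume (%)") +
    theme_minimal()
}

#' Dose at volume (Dx% and Dxcc)
#'
#' `volume_pct`: midpoint-interpolated percentile of the descending dose
#' distribution (the minimum dose to the hottest x% of the structure).
#' `volume_cc`: voxel volumes are accumulated in descending dose order
#' until the requested absolute volume is reached; the dose of the last
#' included voxel is returned (so a single 0.1 cc hotspot voxel defines
#' D0.1cc exactly).
#'
#' @param dose 3D dose array (Gy)
#' @param mask logical structure mask
#' @param volume_pct volume as percent of the structure (0, 100]
#' @param volume_cc volume in cm^3 (alternative to `volume_pct`)
#' @param voxel_mm voxel size (mm; scalar or length 3), needed for
#'   `volume_cc`
#' @return dose in Gy
#' @export
dose_at_volume <- function(dose, mask, volume_pct = NULL, volume_cc = NULL,
                           voxel_mm = NULL) {
  if (!any(mask)) {
    abort("empty structure mask", class = "kvcert_structure_error")
  }
  d <- sort(dose[mask], decreasing = TRUE)
  n <- length(d)
  if (!is.null(volume_pct)) {
    if (volume_pct <= 0 || volume_pct > 100) {
      abort("volume_pct must lie in (0, 100]", class = "kvcert_domain_error")
    }
    # midpoint convention: order statistic k sits at fraction (k - 0.5)/n
    k <- volume_pct / 100 * n + 0.5
    k <- min(max(k, 1), n)
    lo <- floor(k); hi <- ceiling(k)
    return(d[lo] + (k - lo) * (d[hi] - d[lo]))
  }
  if (is.null(volume_cc) || is.null(voxel_mm)) {
    abort("supply volume_pct, or volume_cc with voxel_mm",
          class = "kvcert_domain_error")
  }
  vox_cc <- prod(rep(voxel_mm, length.out = 3)) / 1000
  if (volume_cc <= 0 || volume_cc > n * vox_cc) {
    abort("volume_cc out of (0, structure volume]",
          class = "kvcert_domain_error")
  }
  k <- ceiling(volume_cc / vox_cc - 1e-9)
  d[k]
}

#' Volume receiving at least a dose
#'
#' @param dose 3D dose array (Gy)
#' @param mask logical structure mask
#' @param threshold_gy dose threshold (>= 0)
#' @return percent of the structure volume with dose >= threshold
#' @export
volume_at_dose <- function(dose, mask, threshold_gy) {
  if (!any(mask)) {
    abort("empty structure mask", class = "kvcert_structure_error")
  }
  if (threshold_gy < 0) {
    abort("threshold must be nonnegative", class = "kvcert_domain_error")
  }
  100 * mean(dose[mask] >= threshold_gy)
}

#' Scalar plan metrics for a set of structures
#'
#' Computes the tabulated plan metrics per structure: D98%, D95%, D50%,
#' D2%, Dmean, VxGy for the configured thresholds, and D0.1cc.
#'
#' @param dose 3D dose array (Gy)
#' @param structures named list (or `structure_set`) of logical masks
#' @param voxel_mm voxel size (mm)
#' @param v_thresholds_gy thresholds for the VxGy metrics
#' @return a tibble with `structure`, `metric`, `value`, `unit`
#' @export
plan_metrics <- function(dose, structures, voxel_mm,
                         v_thresholds_gy = c(5, 20)) {
  rows <- lapply(names(structures), function(nm) {
    mask <- structures[[nm]]
    if (!any(mask)) return(NULL)
    d <- dose[mask]
    vox_cc <- prod(rep(voxel_mm, length.out = 3)) / 1000
    vals <- c(
      "D98%" = dose_at_volume(dose, mask, 98),
      "D95%" = dose_at_volume(dose, mask, 95),
      "D50%" = dose_at_volume(dose, mask, 50),
      "D2%" = dose_at_volume(dose, mask, 2),
      "Dmean" = mean(d),
      setNames(vapply(v_thresholds_gy, function(t)
        volume_at_dose(dose, mask, t), numeric(1)),
        sprintf("V%gGy", v_thresholds_gy)),
      "D0.1cc" = if (length(d) * vox_cc >= 0.1)
        dose_at_volume(dose, mask, volume_cc = 0.1, voxel_mm = voxel_mm)
      else max(d))
    tibble(structure = nm, metric = names(vals), value = unname(vals),
           unit = ifelse(grepl("^V", names(vals)), "%", "Gy"))
  })
  bind_rows(rows)
}

#' Check plan metrics against a constraint table
#'
#' A metric exactly at its limit passes (the `<=` convention).
#'
#' @param metrics tibble from [plan_metrics()]
#' @param constraints tibble with columns `structure`, `metric`, `limit`,
#'   and `direction` (`"le"` for upper limits, `"ge"` for lower)
#' @return the constraints tibble with `value`, `pass` and `margin`
#'   columns, with attribute `all_pass`
#' @export
check_constraints <- function(metrics, constraints) {
  if (nrow(constraints) == 0) {
    out <- constraints
    out$value <- numeric(0); out$pass <- logical(0); out$margin <- numeric(0)
    return(structure(out, all_pass = TRUE))
  }
  got <- dplyr::left_join(constraints, metrics,
                          by = c("structure", "metric"))
  if (any(is.na(got$value))) {
    missing <- got[is.na(got$value), ]
    abort(sprintf("constraint references missing metric(s): %s",
                  paste(missing$structure, missing$metric, collapse = ", ")),
          class = "kvcert_config_error")
  }
  dir <- if ("direction" %in% names(got)) got$direction else "le"
  pass <- ifelse(dir == "ge", got$value >= got$limit,
                 got$value <= got$limit)
  margin <- ifelse(dir == "ge", got$value - got$limit,
                   got$limit - got$value)
  out <- got
  out$pass <- pass
  out$margin <- margin
  structure(out, all_pass = all(pass))
}

#' Default organ-at-risk constraint table
#'
#' Placeholder liver / cord / kidney limits for a 40 Gy / 4 fraction
#' schedule. These defaults are conventional working values, not an
#' authoritative protocol; edit to match local practice.
#'
#' @return a constraints tibble usable with [check_constraints()]
#' @export
default_constraints <- function() {
  tibble(
    structure = c("NORMAL_LIVER", "NORMAL_LIVER", "SPINAL_CORD", "BONE",
                  "KIDNEY_L", "KIDNEY_R"),
    metric = c("V20Gy", "Dmean", "D0.1cc", "D0.1cc", "Dmean", "Dmean"),
    limit = c(20, 13, 25, 40, 10, 10),
    direction = "le")
}
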