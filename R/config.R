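# Run configuration (YAML) and the beam-validation report.

#' Default run configuration
#'
#' All physical defaults in one nested list: scanner geometry and beam
#' quality, calibration anchors, phantom parameters, prescription, and
#' transport controls. Serialise with [write_run_config()].
#'
#' @return a named list (class `run_config`)
#' @export
default_run_config <- function() {
  structure(list(
    scanner = list(kvp = 120, focal_to_axis_cm = 62.56,
                   target_hvl_mm = 9.4, inherent_ti_cm = NA,
                   bowtie = list(center_cm = 0.15, edge_cm = 2.8,
                                 fan_half_angle_deg = 22)),
    calibration = list(anchor_low = c(376.2, 11.4),
                       anchor_high = c(1653, 49.4)),
    phantom = list(voxel_mm = 3, gtv_diameter_mm = 30,
                   ptv_margin_mm = 5, noise_sd_hu = 10),
    lipiodol = list(concentration = 50),
    plan = list(prescription_gy = 40, fractions = 4, n_angles = 36,
                field_margin_cm = 0.5, prescribe_to = "GTV"),
    transport = list(n_histories = 1e7, n_batches = 10, cutoff_keV = 1,
                     fluorescence = TRUE),
    seed = 1
  ), class = "run_config")
}

#' Read / write / validate a run configuration
#'
#' YAML round trip with schema validation: unknown keys are rejected, and
#' simulation configurations must carry a seed.
#'
#' @param config a `run_config` list
#' @param path YAML file path
#' @return `read_run_config` returns a validated `run_config`
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path),
          class = "kvcert_config_error")
  }
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname write_run_config
#' @export
validate_run_config <- function(config) {
  template <- unclass(default_run_config())
  check_keys <- function(got, ref, prefix = "") {
    unknown <- setdiff(names(got), names(ref))
    if (length(unknown)) {
      abort(sprintf("unknown config key(s): %s",
                    paste0(prefix, unknown, collapse = ", ")),
            class = "kvcert_config_error")
    }
    for (k in names(got)) {
      if (is.list(ref[[k]]) && !is.null(names(ref[[k]]))) {
        check_keys(got[[k]], ref[[k]], paste0(prefix, k, "."))
      }
    }
  }
  check_keys(config, template)
  if (is.null(config$seed)) {
    abort("config must carry a seed", class = "kvcert_config_error")
  }
  merged <- modifyList(template, config)
  structure(merged, class = "run_config")
}

#' Beam-model validation report
#'
#' Calibrates the inherent filtration to the configured target HVL, then
#' reports the achieved HVL, the effective energy from the aluminum-table
#' inversion, and the off-center ratio profile — the quantities used to
#' validate the scanner beam model against measurement.
#'
#' @param config a `run_config` (default configuration if omitted)
#' @param ocr_offsets_cm lateral offsets for the OCR profile
#' @return a list with `summary` (one-row tibble) and `ocr` (profile
#'   tibble)
#' @export
validate_beam <- function(config = default_run_config(),
                          ocr_offsets_cm = seq(-10, 10, 2)) {
  config <- validate_run_config(unclass(config))
  sc <- config$scanner
  cal <- calibrate_inherent_filtration(sc$target_hvl_mm, sc$kvp)
  eff <- effective_energy_from_hvl(cal$achieved_hvl_mm)
  geom <- scanner_geometry(
    focal_to_axis_cm = sc$focal_to_axis_cm,
    inherent_ti_cm = cal$ti_cm,
    bowtie = bowtie_filter(sc$bowtie$center_cm, sc$bowtie$edge_cm,
                           sc$bowtie$fan_half_angle_deg))
  ocr <- off_center_ratio(geom, ocr_offsets_cm, cal$spectrum)
  summary <- tibble(
    kvp = sc$kvp, inherent_ti_cm = cal$ti_cm,
    hvl_mm = cal$achieved_hvl_mm,
    effective_energy_keV = eff$energy_keV,
    effective_energy_keV_nearest = eff$energy_keV_nearest,
    mean_energy_keV = sum(cal$spectrum$energy_keV * cal$spectrum$fluence),
    ocr_center = ocr$ocr[which.min(abs(ocr$offset_cm))])
  list(summary = summary, ocr = ocr, spectrum = cal$spectrum,
       geometry = geom)
}
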