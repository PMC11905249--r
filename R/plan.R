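# Arc-delivery planning on the kV scanner geometry: beam construction
# around the tumour, prescription normalisation, and the concentration
# sweep.

#' Plan specification
#'
#' @param prescription_gy prescribed dose (Gy), delivered in `fractions`
#'   fractions to the D95% of the prescription structure
#' @param fractions number of fractions
#' @param n_angles number of equispaced gantry angles over 360 degrees
#' @param field_margin_cm aperture margin beyond the projected PTV bounding
#'   box
#' @param prescribe_to structure receiving the D95% prescription
#' @return a `plan_spec` object
#' @export
plan_spec <- function(prescription_gy = 40, fractions = 4, n_angles = 36,
                      field_margin_cm = 0.5, prescribe_to = "GTV") {
  if (prescription_gy <= 0 || fractions < 1 || n_angles < 1) {
    abort("invalid plan specification", class = "kvcert_plan_error")
  }
  structure(list(prescription_gy = prescription_gy, fractions = fractions,
                 n_angles = n_angles, field_margin_cm = field_margin_cm,
                 prescribe_to = prescribe_to), class = "plan_spec")
}

mask_centroid_mm <- function(mask, voxel_mm, origin_mm) {
  idx <- which(mask, arr.ind = TRUE)
  v <- rep(voxel_mm, length.out = 3)
  centers <- sweep(sweep(idx - 0.5, 2, v, `*`), 2, origin_mm, `+`)
  colMeans(centers)
}

#' Build the rotational beam set
#'
#' One beam per gantry angle, rotating in the axial plane about the GTV
#' centroid at the scanner's focal-to-axis distance. Each aperture is the
#' PTV bounding box projected onto the beam's aperture plane plus the field
#' margin.
#'
#' @param phantom a `voxel_phantom`
#' @param structures a `structure_set` with `GTV` and `PTV`
#' @param spec a [plan_spec()]
#' @param geometry a [scanner_geometry()]
#' @param spectrum beam spectrum; default generates one from the geometry's
#'   inherent filtration
#' @return a `beam_set`: beams plus the spectrum and bowtie used for
#'   energy sampling
#' @export
make_arc_plan <- function(phantom, structures, spec = plan_spec(),
                          geometry = scanner_geometry(),
                          spectrum = NULL) {
  if (!any(structures$PTV)) {
    abort("empty PTV", class = "kvcert_plan_error")
  }
  if (is.null(spectrum)) {
    spectrum <- generate_spectrum(120, geometry$inherent_ti_cm)
  }
  iso <- mask_centroid_mm(structures$GTV, phantom$voxel_mm,
                          phantom$origin_mm)
  idx <- which(structures$PTV, arr.ind = TRUE)
  v <- rep(phantom$voxel_mm, length.out = 3)
  pts <- sweep(sweep(idx - 0.5, 2, v, `*`), 2, phantom$origin_mm, `+`)
  rel <- sweep(pts, 2, iso, `-`)
  angles <- seq(0, 360, length.out = spec$n_angles + 1)[-(spec$n_angles + 1)]
  beams <- lapply(angles, function(a) {
    th <- a * pi / 180
    axis <- c(cos(th), sin(th), 0)
    b <- beam_spec(iso, axis, 1, 1,
                   focal_distance_cm = geometry$focal_to_axis_cm)
    # project PTV extent (+ half a voxel) onto the aperture axes
    half_u <- max(abs(rel %*% b$uax)) / 10 + max(v) / 20 +
      spec$field_margin_cm
    half_v <- max(abs(rel %*% b$vax)) / 10 + max(v) / 20 +
      spec$field_margin_cm
    b$half_u <- half_u
    b$half_v <- half_v
    b$gantry_deg <- a
    b
  })
  structure(list(beams = beams, spectrum = spectrum,
                 bowtie = geometry$bowtie, iso_mm = iso, spec = spec,
                 geometry = geometry),
            class = "beam_set")
}

#' @export
print.beam_set <- function(x, ...) {
  cat(sprintf("<beam set: %d gantry angles, aperture %.1f x %.1f cm, iso (%s) mm>\n",
              length(x$beams), 2 * x$beams[[1]]$half_u,
              2 * x$beams[[1]]$half_v,
              paste(signif(x$iso_mm, 3), collapse = ", ")))
  invisible(x)
}

#' Compute a normalised plan
#'
#' Accumulates the arc dose with equal beam weights, then scales the grid
#' so that D95% of the prescription structure equals the prescribed dose.
#'
#' @param phantom a material-assigned `voxel_phantom`
#' @param structures a `structure_set`
#' @param beams a `beam_set` from [make_arc_plan()]
#' @param config a [transport_config()]
#' @return a `plan_result`: normalised `dose` (Gy), `scale_factor`,
#'   `metrics` ([plan_metrics()] tibble), the underlying `dose_grid`, and a
#'   `manifest`
#' @export
compute_plan <- function(phantom, structures, beams,
                         config = transport_config()) {
  spec <- beams$spec
  grid <- run_simulation(phantom, beams, config)
  raw <- dose_gy(grid)
  target_mask <- structures[[spec$prescribe_to]]
  d95_raw <- dose_at_volume(raw, target_mask, 95)
  if (!is.finite(d95_raw) || d95_raw <= 0) {
    abort("raw D95% of the prescription structure is zero",
          class = "kvcert_normalisation_error")
  }
  scale <- spec$prescription_gy / d95_raw
  dose <- raw * scale
  metrics <- plan_metrics(dose, structures, phantom$voxel_mm)
  structure(list(
    dose = dose, scale_factor = scale, metrics = metrics,
    dose_grid = grid, plan = spec,
    manifest = list(seed = config$seed, n_histories = grid$histories,
                    n_batches = grid$n_batches,
                    concentration = phantom$params$concentration %||% NA,
                    prescribe_to = spec$prescribe_to,
                    prescription_gy = spec$prescription_gy,
                    fractions = spec$fractions)),
    class = "plan_result")
}

#' @export
print.plan_result <- function(x, ...) {
  cat(sprintf("<plan result: %g Gy / %d fr to D95%%(%s); scale %.3g>\n",
              x$plan$prescription_gy, x$plan$fractions, x$plan$prescribe_to,
              x$scale_factor))
  print(glance(x))
  invisible(x)
}

#' @method tidy plan_result
#' @param x a `plan_result`
#' @param ... unused
#' @rdname compute_plan
#' @export
tidy.plan_result <- function(x, ...) x$metrics

#' @method glance plan_result
#' @rdname compute_plan
#' @export
glance.plan_result <- function(x, ...) {
  m <- x$metrics
  gtv <- m[m$structure == "GTV", ]
  get <- function(k) {
    v <- gtv$value[gtv$metric == k]
    if (length(v)) v else NA_real_
  }
  tibble(d95_gtv_gy = get("D95%"), d2_gtv_gy = get("D2%"),
         d50_gtv_gy = get("D50%"), dmean_gtv_gy = get("Dmean"),
         d2_pct_of_rx = 100 * get("D2%") / x$plan$prescription_gy,
         dose_per_fraction_gy = x$plan$prescription_gy / x$plan$fractions,
         max_rel_se_hot = estimate_uncertainty(x$dose_grid)$max_rel_se_hot)
}

#' Concentration sweep
#'
#' Runs the full pipeline (phantom build, material assignment, arc
#' delivery, prescription normalisation, DVH metrics) once per
#' concentration, sharing the phantom geometry, noise seed and transport
#' seeds across concentrations.
#'
#' @param concentrations iodinated-agent concentrations (mg/mL)
#' @param params phantom parameters ([abdomen_params()])
#' @param spec a [plan_spec()]
#' @param geometry a [scanner_geometry()]
#' @param spectrum beam spectrum (calibrate once and pass in to avoid
#'   recalibration per run)
#' @param config a [transport_config()]
#' @param seed phantom noise seed
#' @return a tibble of plan metrics with a `concentration` column, one
#'   block per concentration
#' @export
concentration_sweep <- function(concentrations,
                                params = abdomen_params(),
                                spec = plan_spec(),
                                geometry = scanner_geometry(),
                                spectrum = NULL,
                                config = transport_config(),
                                seed = 1) {
  if (any(concentrations < 0 | concentrations > 480)) {
    abort("concentrations must lie in [0, 480] mg/mL",
          class = "kvcert_domain_error")
  }
  if (is.null(spectrum)) {
    spectrum <- generate_spectrum(120, geometry$inherent_ti_cm)
  }
  rows <- lapply(concentrations, function(conc) {
    p <- params
    p$concentration <- conc
    ab <- build_synthetic_abdomen(p, seed = seed)
    ph <- assign_materials(ab$phantom, ab$structures,
                           lipiodol_material(conc))
    beams <- make_arc_plan(ph, ab$structures, spec, geometry, spectrum)
    res <- compute_plan(ph, ab$structures, beams, config)
    dplyr::mutate(res$metrics, concentration = conc, .before = 1)
  })
  bind_rows(rows)
}
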