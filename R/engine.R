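# R-side surface of the Monte Carlo engine: cross-section table assembly,
# beam construction, transport configuration, dose grids with batch
# statistics, and the two in-silico validation benches.

KEV_TO_J <- 1.602176634e-16

#' Transport configuration
#'
#' @param n_histories total photon histories
#' @param n_batches number of statistical batches (>= 2)
#' @param cutoff_keV photon cutoff energy; photons falling below are
#'   terminated and booked as discarded
#' @param seed RNG seed (integer-valued)
#' @param fluorescence transport single-line K-alpha fluorescence for
#'   absorbers with Z >= 20
#' @param primary_only terminate photons at their first real interaction
#'   (Beer-Lambert / narrow-beam studies)
#' @param uncertainty_target optional relative standard error target; the
#'   run is extended in whole-run increments until the max relative SE over
#'   voxels above 50% of the maximum dose falls below it
#' @param max_rounds cap on the number of increments for targeted runs
#' @return a `transport_config` object
#' @export
transport_config <- function(n_histories = 1e6, n_batches = 10,
                             cutoff_keV = 1, seed = 1,
                             fluorescence = TRUE, primary_only = FALSE,
                             uncertainty_target = NULL, max_rounds = 30) {
  if (n_batches < 2 || n_histories < n_batches) {
    abort("need n_histories >= n_batches >= 2",
          class = "kvcert_config_error")
  }
  if (cutoff_keV < 1) {
    abort("photon cutoff must be >= 1 keV (table range)",
          class = "kvcert_config_error")
  }
  structure(list(n_histories = n_histories, n_batches = n_batches,
                 cutoff_keV = cutoff_keV, seed = seed,
                 fluorescence = fluorescence, primary_only = primary_only,
                 uncertainty_target = uncertainty_target,
                 max_rounds = max_rounds),
            class = "transport_config")
}

# fine energy grid shared by all engine lookups
engine_energy_grid <- function() seq(1, 150, by = 0.25)

# assemble per-material engine tables from the bundled cross sections
build_engine_tables <- function(materials) {
  egrid <- engine_energy_grid()
  n_e <- length(egrid)
  n_m <- length(materials)
  mu_mass <- matrix(0, n_e, n_m)
  p_pe <- matrix(0, n_e, n_m)
  p_incoh <- matrix(0, n_e, n_m)
  fl_frac <- matrix(0, n_e, n_m)
  fl_omega <- numeric(n_m)
  fl_eka <- numeric(n_m)
  fl_edge <- rep(1e9, n_m)
  fluo <- .fluorescence_registry
  for (j in seq_len(n_m)) {
    m <- as_material(materials[[j]])
    tot <- mixture_mu(m, egrid, "total")
    pe <- mixture_mu(m, egrid, "photoelectric")
    inc <- mixture_mu(m, egrid, "incoherent")
    mu_mass[, j] <- tot
    p_pe[, j] <- pe / tot
    p_incoh[, j] <- inc / tot
    present <- intersect(names(m$elements), fluo$element)
    if (length(present)) {
      w <- m$elements[present]
      sym <- present[which.max(w)]
      row <- fluo[fluo$element == sym, ]
      fl_omega[j] <- row$fluorescence_yield
      fl_eka[j] <- row$kalpha_keV
      fl_edge[j] <- row$k_edge_keV
      pe_el <- att_interp(load_att_table(sym), egrid, "mu_pe")
      frac <- m$elements[[sym]] * pe_el / pmax(pe, 1e-30)
      frac[egrid <= row$k_edge_keV] <- 0
      fl_frac[, j] <- pmin(frac, 1)
    }
  }
  list(egrid = egrid, mu_mass = mu_mass, p_pe = p_pe, p_incoh = p_incoh,
       fl_frac = fl_frac, fl_omega = fl_omega, fl_eka = fl_eka,
       fl_edge = fl_edge)
}

#' Define a single beam
#'
#' A beam is a rectangular aperture at the isocenter plane, irradiated
#' either from a focal spot (divergent) or as a parallel field.
#'
#' @param iso_mm isocenter / aperture centre (mm, length 3)
#' @param axis unit beam direction (length 3)
#' @param half_u_cm,half_v_cm aperture half-widths at the isocenter plane
#'   (cm); `u` spans the fan direction, `v` the axial direction
#' @param focal_distance_cm focal spot to isocenter distance (cm), ignored
#'   for parallel beams
#' @param parallel parallel (TRUE) or point-source (FALSE) geometry
#' @return a `beam_spec` list
#' @export
beam_spec <- function(iso_mm, axis, half_u_cm, half_v_cm,
                      focal_distance_cm = 62.56, parallel = FALSE) {
  axis <- axis / sqrt(sum(axis^2))
  # aperture-plane basis: u perpendicular to axis in the least-aligned
  # cardinal plane, v completes the triad
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  uax <- c(axis[2] * ref[3] - axis[3] * ref[2],
           axis[3] * ref[1] - axis[1] * ref[3],
           axis[1] * ref[2] - axis[2] * ref[1])
  uax <- uax / sqrt(sum(uax^2))
  vax <- c(uax[2] * axis[3] - uax[3] * axis[2],
           uax[3] * axis[1] - uax[1] * axis[3],
           uax[1] * axis[2] - uax[2] * axis[1])
  iso_cm <- iso_mm / 10
  list(iso = iso_cm, axis = axis, uax = uax, vax = vax,
       focal = iso_cm - axis * focal_distance_cm,
       focal_distance_cm = focal_distance_cm,
       half_u = half_u_cm, half_v = half_v_cm, parallel = parallel)
}

# attach energy-sampling CDFs to beams: per-beam angular sub-bins through
# the bowtie (if any), inverse-CDF over the spectrum bins
make_beam_list <- function(beams, spectrum, bowtie = NULL,
                           n_angle_bins = 8) {
  edges <- attr(spectrum, "bin_edges")
  f0 <- spectrum$fluence
  lapply(beams, function(b) {
    if (is.null(bowtie) || b$parallel) {
      cdf <- matrix(cumsum(f0) / sum(f0), ncol = 1)
    } else {
      half_fan <- atan(b$half_u / b$focal_distance_cm)
      cdf <- vapply(seq_len(n_angle_bins), function(k) {
        ang <- (k - 0.5) / n_angle_bins * half_fan
        cumsum(spectrum_at_angle(spectrum, bowtie, ang))
      }, numeric(length(f0)))
    }
    c(b, list(cdf = cdf, spec_edges = edges))
  })
}

run_transport_once <- function(phantom, beam_list, tabs, config,
                               seed, exit_weight = numeric(0)) {
  rho <- phantom$density
  mat0 <- phantom$material_index - 1L  # 0-based for C++
  rho_max <- vapply(seq_along(phantom$materials), function(j) {
    sel <- phantom$material_index == j
    if (any(sel)) max(rho[sel]) else 0
  }, numeric(1))
  mu_majorant <- apply(sweep(tabs$mu_mass, 2, rho_max, `*`), 1, max)
  mc_transport(shape = dim(rho), voxel_cm = rep(phantom$voxel_mm / 10, length.out = 3),
               origin_cm = phantom$origin_mm / 10,
               material_index = as.integer(mat0), density = as.numeric(rho),
               egrid = tabs$egrid, mu_mass = tabs$mu_mass,
               p_pe = tabs$p_pe, p_incoh = tabs$p_incoh,
               fl_frac = tabs$fl_frac, fl_omega = tabs$fl_omega,
               fl_eka = tabs$fl_eka, fl_edge = tabs$fl_edge,
               mu_majorant = mu_majorant, beams_in = beam_list,
               cutoff_keV = config$cutoff_keV,
               n_histories = config$n_histories,
               n_batches = config$n_batches, seed = seed,
               primary_only = config$primary_only,
               fluorescence = config$fluorescence,
               exit_weight = exit_weight)
}

new_dose_grid <- function(res, phantom) {
  dims <- dim(phantom$density)
  structure(list(
    edep_sum = array(res$edep_sum, dims),
    edep_sumsq = array(res$edep_sumsq, dims),
    n_batches = res$n_batches,
    histories = res$histories_per_batch * res$n_batches,
    audit = res$audit,
    exit_tally = res$exit_tally,
    voxel_mm = phantom$voxel_mm,
    density = phantom$density,
    origin_mm = phantom$origin_mm), class = "dose_grid")
}

merge_dose_grids <- function(a, b) {
  a$edep_sum <- a$edep_sum + b$edep_sum
  a$edep_sumsq <- a$edep_sumsq + b$edep_sumsq
  a$n_batches <- a$n_batches + b$n_batches
  a$histories <- a$histories + b$histories
  a$audit <- rbind(a$audit, b$audit)
  a$exit_tally <- c(a$exit_tally, b$exit_tally)
  a
}

#' Run the Monte Carlo transport
#'
#' Transports photons through the phantom by Woodcock delta tracking and
#' returns a [dose_grid] with per-batch statistics. Deterministic for a
#' fixed seed (single threaded). If `config$uncertainty_target` is set, the
#' run is repeated in whole increments (fresh seeds derived from the base
#' seed) until the maximum relative standard error over voxels above 50% of
#' the maximum dose reaches the target.
#'
#' @param phantom a [build_synthetic_abdomen()] phantom (materials
#'   assigned) or any `voxel_phantom`
#' @param beams a beam set from [make_arc_plan()] or a list of
#'   [beam_spec()] plus `spectrum` via the `spectrum` argument
#' @param config a [transport_config()]
#' @param spectrum spectrum used when `beams` is a plain list of
#'   `beam_spec`s
#' @param bowtie optional bowtie filter applied to per-beam spectra
#' @return a `dose_grid`
#' @export
run_simulation <- function(phantom, beams, config = transport_config(),
                           spectrum = NULL, bowtie = NULL) {
  if (inherits(beams, "beam_set")) {
    spectrum <- beams$spectrum
    bowtie <- beams$bowtie
    beams <- beams$beams
  }
  if (is.null(spectrum)) {
    abort("a spectrum is required (directly or via the beam set)",
          class = "kvcert_config_error")
  }
  if (!length(beams)) {
    abort("no beams supplied", class = "kvcert_plan_error")
  }
  tabs <- build_engine_tables(phantom$materials)
  beam_list <- make_beam_list(beams, spectrum, bowtie)
  res <- run_transport_once(phantom, beam_list, tabs, config, config$seed)
  grid <- new_dose_grid(res, phantom)
  if (!is.null(config$uncertainty_target)) {
    round <- 1L
    while (estimate_uncertainty(grid)$max_rel_se_hot >
           config$uncertainty_target && round < config$max_rounds) {
      res2 <- run_transport_once(phantom, beam_list, tabs, config,
                                 config$seed + round * 1000003)
      grid <- merge_dose_grids(grid, new_dose_grid(res2, phantom))
      round <- round + 1L
    }
  }
  grid
}

#' @export
print.dose_grid <- function(x, ...) {
  unc <- estimate_uncertainty(x)
  cat(sprintf("<dose grid %s, %g histories in %d batches, max rel SE (hot) %.2f%%>\n",
              paste(dim(x$edep_sum), collapse = "x"), x$histories,
              x$n_batches, 100 * unc$max_rel_se_hot))
  invisible(x)
}

#' Dose in Gy from a dose grid
#'
#' Converts accumulated energy deposition (keV) to absorbed dose via the
#' voxel masses, with an arbitrary overall scale (set by prescription
#' normalisation in [compute_plan()]).
#'
#' @param grid a `dose_grid`
#' @param scale multiplicative factor (Gy per raw Gy-equivalent)
#' @return 3D array of dose (Gy)
#' @export
dose_gy <- function(grid, scale = 1) {
  vox_cm3 <- prod(rep(grid$voxel_mm / 10, length.out = 3))
  mass_kg <- grid$density * vox_cm3 * 1e-3
  scale * grid$edep_sum * KEV_TO_J / mass_kg
}

#' Batch-based statistical uncertainty
#'
#' Relative standard error of the accumulated energy deposition per voxel
#' from batch-to-batch variance, and the summary used by the 1% precision
#' criterion: the maximum relative SE over voxels receiving more than 50%
#' of the maximum dose.
#'
#' The hot-voxel set is restricted to tissue-like voxels (density at least
#' `min_density`): near-zero-mass air voxels otherwise dominate the
#' maximum dose through single-interaction spikes.
#'
#' @param grid a `dose_grid` with at least two batches
#' @param min_density density cutoff (g/cm^3) for the hot-voxel summary
#' @return a list with `rel_se` (array), `max_rel_se_hot`, `n_hot`
#' @export
estimate_uncertainty <- function(grid, min_density = 0.5) {
  B <- grid$n_batches
  if (B < 2) {
    abort("need at least two batches for uncertainty estimation",
          class = "kvcert_statistics_error")
  }
  s <- grid$edep_sum
  ss <- grid$edep_sumsq
  var_b <- pmax(ss - s^2 / B, 0) / (B - 1)
  se_total <- sqrt(B * var_b)
  rel <- array(0, dim(s))
  pos <- s > 0
  rel[pos] <- se_total[pos] / s[pos]
  dose <- dose_gy(grid)
  tissue <- grid$density >= min_density
  dmax <- if (any(tissue)) max(dose[tissue]) else max(dose)
  hot <- dose > 0.5 * dmax & tissue
  list(rel_se = rel,
       max_rel_se_hot = if (any(hot)) max(rel[hot]) else NA_real_,
       n_hot = sum(hot))
}

#' Monoenergetic "spectrum"
#'
#' Single-line spectrum container usable wherever a [generate_spectrum()]
#' result is accepted (tests, effective-energy studies).
#'
#' @param energy_keV line energy
#' @return an `xray_spectrum` with one bin of zero width
#' @export
monoenergetic_spectrum <- function(energy_keV) {
  out <- tibble(energy_keV = energy_keV, fluence = 1)
  structure(out, class = c("xray_spectrum", class(out)),
            kvp = energy_keV, bin_edges = c(energy_keV, energy_keV),
            inherent_ti_cm = 0)
}

#' Interaction channel probabilities
#'
#' Probability of each interaction channel (photoelectric, incoherent,
#' coherent) at a given energy in a material, proportional to the partial
#' mass attenuation coefficients.
#'
#' @param material a material name or [material_composition()]
#' @param energy_keV photon energy
#' @return a tibble with `channel` and `probability` (sums to 1)
#' @export
interaction_probabilities <- function(material, energy_keV) {
  tot <- mixture_mu(material, energy_keV, "total")
  p <- c(mixture_mu(material, energy_keV, "photoelectric"),
         mixture_mu(material, energy_keV, "incoherent"),
         mixture_mu(material, energy_keV, "coherent"))
  tibble(channel = c("photoelectric", "incoherent", "coherent"),
         probability = p / sum(p))
}

#' Sample interaction channels
#'
#' @param n number of draws
#' @param material material name or composition
#' @param energy_keV photon energy
#' @param seed RNG seed
#' @return character vector of sampled channels
#' @export
sample_interaction <- function(n, material, energy_keV, seed = 1) {
  p <- interaction_probabilities(material, energy_keV)
  set.seed(seed)
  sample(p$channel, n, replace = TRUE, prob = p$probability)
}

#' Sample the Klein-Nishina scattering kernel
#'
#' Composition-rejection sampling of the free-electron Compton kernel (the
#' same sampler the transport engine uses).
#'
#' @param n number of samples
#' @param energy_keV incident photon energy
#' @param seed RNG seed
#' @return a tibble with `scattered_keV` and `cos_theta`
#' @export
sample_compton <- function(n, energy_keV, seed = 1) {
  m <- mc_sample_compton(n, energy_keV, seed)
  tibble(scattered_keV = m[, 1], cos_theta = m[, 2])
}

#' Aluminum HVL bench
#'
#' Narrow-beam air-kerma transmission versus added aluminum, either
#' analytically (spectrum-weighted Beer-Lambert, the ionization-chamber
#' surrogate) or by transporting primaries through an aluminum slab and
#' tallying never-scattered photons at the exit with air-kerma weighting.
#' The HVL is read off the transmission curve by monotone log-linear
#' interpolation.
#'
#' @param spectrum an `xray_spectrum`
#' @param thicknesses_mm added aluminum thicknesses; must span the
#'   half-transmission point
#' @param mode `"analytic"` or `"transport"`
#' @param n_histories histories per thickness (transport mode)
#' @param seed RNG seed (transport mode)
#' @return a tibble of `thickness_mm`, `transmission` (and `se` in
#'   transport mode) with attribute `hvl_mm`
#' @export
simulate_hvl_bench <- function(spectrum, thicknesses_mm = seq(0, 14, 2),
                               mode = c("analytic", "transport"),
                               n_histories = 2e5, seed = 1) {
  mode <- match.arg(mode)
  thicknesses_mm <- sort(thicknesses_mm)
  if (mode == "analytic") {
    tr <- spectrum_transmission_al(spectrum, thicknesses_mm)
    se <- rep(0, length(tr))
  } else {
    egrid <- engine_energy_grid()
    w_air <- mixture_mu("air", egrid, "mu_en")
    beam <- beam_spec(c(0, -100, 0), c(0, 1, 0), 0.05, 0.05,
                      parallel = TRUE)
    cfg <- transport_config(n_histories = n_histories, n_batches = 10,
                            seed = seed, primary_only = TRUE)
    run_slab <- function(material, t_cm) {
      ph <- slab_phantom(list(list(material = material,
                                   thickness_cm = t_cm)),
                         lateral_cm = 2, n_depth = 4, n_lateral = 2)
      tabs <- build_engine_tables(ph$materials)
      bl <- make_beam_list(list(beam), spectrum)
      run_transport_once(ph, bl, tabs, cfg, seed, exit_weight = w_air)$exit_tally
    }
    rel_se <- function(v) stats::sd(v) / sqrt(length(v)) / mean(v)
    ref <- run_slab(standard_material("air"), 1)
    vals <- lapply(thicknesses_mm, function(t_mm) {
      if (t_mm <= 0) ref
      else run_slab(standard_material("aluminum"), t_mm / 10)
    })
    tr <- vapply(vals, function(v) sum(v) / sum(ref), numeric(1))
    se <- vapply(seq_along(vals), function(i) {
      if (thicknesses_mm[i] <= 0) return(0)
      tr[i] * sqrt(rel_se(vals[[i]])^2 + rel_se(ref)^2)
    }, numeric(1))
  }
  if (min(tr) > 0.5 || max(tr) < 0.5) {
    abort("thickness list does not bracket half transmission",
          class = "kvcert_bracketing_error")
  }
  hvl <- approx(log(tr), thicknesses_mm, xout = log(0.5))$y
  out <- tibble(thickness_mm = thicknesses_mm, transmission = tr, se = se)
  structure(out, class = c("hvl_bench", class(out)), hvl_mm = hvl)
}

# layered slab phantom along +y; layers from y = 0; anisotropic voxels
slab_phantom <- function(layers, lateral_cm = 3, n_depth = 40,
                         n_lateral = 12, backing = "air") {
  total_cm <- sum(vapply(layers, `[[`, numeric(1), "thickness_cm"))
  dz <- total_cm / n_depth
  dlat <- lateral_cm / n_lateral
  mats <- c(lapply(layers, `[[`, "material"),
            list(standard_material(backing)))
  names(mats) <- make.unique(
    c(vapply(layers, function(l) l$material$name, ""), backing))
  idx <- array(length(mats), dim = c(n_lateral, n_depth, n_lateral))
  depth <- (seq_len(n_depth) - 0.5) * dz
  bounds <- cumsum(vapply(layers, `[[`, numeric(1), "thickness_cm"))
  layer_of <- findInterval(depth, c(0, bounds), rightmost.closed = TRUE)
  layer_of[layer_of > length(layers)] <- length(mats)
  for (iy in seq_len(n_depth)) idx[, iy, ] <- layer_of[iy]
  dens <- array(0, dim(idx))
  for (j in seq_along(mats)) dens[idx == j] <- mats[[j]]$density
  structure(list(
    hu = NULL, voxel_mm = c(dlat, dz, dlat) * 10,
    origin_mm = c(-lateral_cm / 2, 0, -lateral_cm / 2) * 10,
    materials = mats, material_index = idx, density = dens),
    class = "voxel_phantom")
}

#' Contrast dose-enhancement bench
#'
#' Replicates the slab validation geometry: a point source at a given SSD,
#' a PMMA build-up slab, a contrast layer (iodinated water at the requested
#' concentration) and a water backing. Two transports in identical geometry
#' (contrast vs. plain water) give the central-axis percent enhancement
#' \eqn{100 (D_c/D_w - 1)} versus depth.
#'
#' @param spectrum incident spectrum
#' @param concentration iodine concentration in the contrast layer (mg/mL)
#' @param n_histories histories per arm
#' @param seed RNG seed (shared by both arms)
#' @param ssd_cm source-to-surface distance
#' @param pmma_cm PMMA slab thickness
#' @param contrast_cm contrast layer thickness
#' @param field_cm square field size at the surface
#' @param depth_res_cm depth scoring resolution
#' @return a tibble of depth, central-axis doses, relative SEs and
#'   `enhancement_pct`, with attribute `max_enhancement_pct` (maximum over
#'   contrast-layer depths)
#' @export
simulate_enhancement_bench <- function(spectrum, concentration = 100,
                                       n_histories = 2e6, seed = 1,
                                       ssd_cm = 15, pmma_cm = 4.8,
                                       contrast_cm = 3, field_cm = 4,
                                       depth_res_cm = 0.25) {
  if (concentration < 0) {
    abort("concentration must be nonnegative", class = "kvcert_domain_error")
  }
  total_cm <- pmma_cm + contrast_cm + 2
  n_depth <- round(total_cm / depth_res_cm)
  contrast <- lipiodol_material(concentration, base = "water")
  build <- function(layer2) {
    slab_phantom(list(
      list(material = standard_material("pmma"), thickness_cm = pmma_cm),
      list(material = layer2, thickness_cm = contrast_cm),
      list(material = standard_material("water"), thickness_cm = 2)),
      lateral_cm = field_cm + 2, n_depth = n_depth, n_lateral = 12,
      backing = "air")
  }
  cfg <- transport_config(n_histories = n_histories, n_batches = 10,
                          seed = seed)
  run_arm <- function(ph) {
    beam <- beam_spec(c(0, 0, 0), c(0, 1, 0), field_cm / 2, field_cm / 2,
                      focal_distance_cm = ssd_cm)
    run_simulation(ph, list(beam), cfg, spectrum = spectrum)
  }
  g_c <- run_arm(build(contrast))
  g_w <- run_arm(build(standard_material("water")))
  dims <- dim(g_c$edep_sum)
  ctr <- dims[1] %/% 2 + c(0L, 1L)
  ctr <- ctr[ctr >= 1 & ctr <= dims[1]]
  axis_dose <- function(g) {
    apply(g$edep_sum[ctr, , ctr, drop = FALSE], 2, sum) /
      apply(g$density[ctr, , ctr, drop = FALSE], 2, sum)
  }
  axis_se <- function(g) {
    rel <- estimate_uncertainty(g)$rel_se
    apply(rel[ctr, , ctr, drop = FALSE], 2, mean)
  }
  d_c <- axis_dose(g_c)
  d_w <- axis_dose(g_w)
  depth <- (seq_len(dims[2]) - 0.5) * rep(g_c$voxel_mm, length.out = 3)[2] / 10
  ok <- d_w > 0
  enh <- rep(NA_real_, length(d_w))
  enh[ok] <- 100 * (d_c[ok] / d_w[ok] - 1)
  out <- tibble(depth_cm = depth, dose_contrast = d_c, dose_water = d_w,
                rel_se_contrast = axis_se(g_c), rel_se_water = axis_se(g_w),
                enhancement_pct = enh)
  in_contrast <- depth >= pmma_cm & depth <= pmma_cm + contrast_cm & ok
  structure(out, class = c("enhancement_bench", class(out)),
            max_enhancement_pct = max(enh[in_contrast], na.rm = TRUE),
            concentration = concentration)
}

#' @method autoplot enhancement_bench
#' @export
autoplot.enhancement_bench <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$depth_cm,
                                y = .data$enhancement_pct)) +
    geom_line() +
    labs(x = "depth (cm)", y = "dose enhancement (%)",
         title = sprintf("%g mg/mL contrast layer",
                         attr(object, "concentration"))) +
    theme_minimal()
}
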