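# Synthetic abdominal voxel phantom: parametric anatomy (body, liver,
# vertebral column with cord canal, kidneys), a spherical iodinated tumour
# insert, structure masks, the clinical tumour-HU surrogate sampler, and
# phantom I/O.

#' Default parameters of the synthetic abdomen
#'
#' All lengths in mm. Organ positions and sizes are chosen so the spinal
#' cord and kidneys sit posterior to the liver, outside the primary arc
#' field around the tumour.
#'
#' @param voxel_mm isotropic voxel size (1-5 mm)
#' @param gtv_diameter_mm tumour (GTV) diameter
#' @param concentration iodinated-agent concentration filling the GTV
#'   (mg/mL)
#' @param noise_sd_hu Gaussian HU texture noise
#' @return a named list of phantom parameters
#' @export
abdomen_params <- function(voxel_mm = 3, gtv_diameter_mm = 30,
                           concentration = 50, noise_sd_hu = 10) {
  if (voxel_mm < 1 || voxel_mm > 5) {
    abort("voxel_mm must lie in [1, 5]", class = "kvcert_domain_error")
  }
  list(
    voxel_mm = voxel_mm,
    extent_mm = c(340, 240, 180),          # grid extent (x lateral,
                                           # y anterior-posterior, z axial)
    body_semiaxes_mm = c(160, 110),
    liver_center_mm = c(55, 10, 5),
    liver_semiaxes_mm = c(85, 60, 70),
    gtv_diameter_mm = gtv_diameter_mm,
    ptv_margin_mm = 5,
    vertebra_center_y_mm = -75,
    vertebra_radius_mm = 16,
    canal_radius_mm = 5,
    kidney_centers_mm = list(L = c(-62, -55, -20), R = c(62, -55, -20)),
    kidney_semiaxes_mm = c(25, 18, 45),
    hu = c(soft = 40, liver = 60, bone = 700, cord = 40, kidney = 35,
           air = -1000),
    noise_sd_hu = noise_sd_hu,
    concentration = concentration
  )
}

#' Build the synthetic abdominal phantom and its structure set
#'
#' Elliptic-cylinder soft-tissue body containing a liver ellipsoid, a bone
#' vertebral column with a central cord canal, two kidneys, and a spherical
#' GTV centred in the liver. HU values carry Gaussian texture noise; the
#' GTV HU is set from the concentration calibration. Materials and density
#' are then assigned with [assign_materials()].
#'
#' @param params parameter list from [abdomen_params()]
#' @param seed RNG seed for the HU noise
#' @param calibration HU calibration for the GTV filling
#' @return a list with `phantom` (a `voxel_phantom`) and `structures`
#'   (a `structure_set` of logical masks: BODY, LIVER, GTV, PTV,
#'   NORMAL_LIVER, BONE, SPINAL_CORD, KIDNEY_L, KIDNEY_R)
#' @export
build_synthetic_abdomen <- function(params = abdomen_params(), seed = 1,
                                    calibration = lipiodol_calibration()) {
  vox <- params$voxel_mm
  n <- round(params$extent_mm / vox)
  origin <- -params$extent_mm / 2
  cx <- origin[1] + (seq_len(n[1]) - 0.5) * vox
  cy <- origin[2] + (seq_len(n[2]) - 0.5) * vox
  cz <- origin[3] + (seq_len(n[3]) - 0.5) * vox
  X <- array(rep(cx, times = n[2] * n[3]), n)
  Y <- array(rep(rep(cy, each = n[1]), times = n[3]), n)
  Z <- array(rep(cz, each = n[1] * n[2]), n)

  ellipsoid <- function(c0, s) {
    ((X - c0[1]) / s[1])^2 + ((Y - c0[2]) / s[2])^2 +
      ((Z - c0[3]) / s[3])^2 <= 1
  }
  body <- (X / params$body_semiaxes_mm[1])^2 +
    (Y / params$body_semiaxes_mm[2])^2 <= 1
  liver <- ellipsoid(params$liver_center_mm, params$liver_semiaxes_mm) & body
  gtv_center <- params$liver_center_mm
  r_gtv <- params$gtv_diameter_mm / 2
  gtv <- ellipsoid(gtv_center, rep(r_gtv, 3))
  if (any(gtv & !liver)) {
    abort("GTV is not fully inside the liver",
          class = "kvcert_geometry_error")
  }
  vert <- (X^2 + (Y - params$vertebra_center_y_mm)^2) <=
    params$vertebra_radius_mm^2 & body
  canal <- (X^2 + (Y - params$vertebra_center_y_mm)^2) <=
    params$canal_radius_mm^2 & body
  bone <- vert & !canal
  cord <- canal
  kid_l <- ellipsoid(params$kidney_centers_mm$L, params$kidney_semiaxes_mm) &
    body & !vert
  kid_r <- ellipsoid(params$kidney_centers_mm$R, params$kidney_semiaxes_mm) &
    body & !vert
  ptv <- expand_margin(gtv, params$ptv_margin_mm, vox)

  set.seed(seed)
  hu <- array(params$hu[["air"]], n)
  hu[body] <- params$hu[["soft"]]
  hu[liver] <- params$hu[["liver"]]
  hu[kid_l | kid_r] <- params$hu[["kidney"]]
  hu[bone] <- params$hu[["bone"]]
  hu[cord] <- params$hu[["cord"]]
  noise <- array(rnorm(prod(n), 0, params$noise_sd_hu), n)
  hu[body] <- hu[body] + noise[body]
  gtv_hu <- suppressWarnings(
    concentration_to_hu(calibration, params$concentration))
  hu[gtv] <- gtv_hu + noise[gtv]

  phantom <- structure(list(
    hu = hu, voxel_mm = vox, origin_mm = origin,
    materials = NULL, material_index = NULL, density = NULL,
    params = params, seed = seed), class = "voxel_phantom")
  structures <- structure(list(
    BODY = body, LIVER = liver, GTV = gtv, PTV = ptv,
    NORMAL_LIVER = liver & !gtv, BONE = bone, SPINAL_CORD = cord,
    KIDNEY_L = kid_l, KIDNEY_R = kid_r),
    class = "structure_set", voxel_mm = vox)
  list(phantom = phantom, structures = structures)
}

#' @export
print.voxel_phantom <- function(x, ...) {
  cat(sprintf("<voxel phantom %s, voxel %s mm, materials: %s>\n",
              paste(dim(x$hu %||% x$density), collapse = "x"),
              paste(signif(x$voxel_mm, 3), collapse = "x"),
              if (is.null(x$materials)) "unassigned"
              else paste(names(x$materials), collapse = ", ")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Isotropic margin expansion of a mask
#'
#' Morphological dilation by a Euclidean ball of radius `margin_mm`,
#' applied between voxel centres with a half-voxel compensation: dilating a
#' voxelised sphere then approximates the dilation of the continuous
#' sphere (a pure centre-to-centre ball systematically under-reaches along
#' the diagonals at coarse voxels).
#'
#' @param mask logical 3D array
#' @param margin_mm margin radius (mm, >= 0)
#' @param voxel_mm voxel size (mm), scalar or length 3
#' @return dilated logical array
#' @export
expand_margin <- function(mask, margin_mm, voxel_mm) {
  if (margin_mm < 0) {
    abort("margin must be nonnegative", class = "kvcert_domain_error")
  }
  if (margin_mm == 0) return(mask)
  v <- rep(voxel_mm, length.out = 3)
  eff <- margin_mm + 0.5 * mean(v)
  r <- ceiling(eff / v)
  off <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  d2 <- (off$dx * v[1])^2 + (off$dy * v[2])^2 + (off$dz * v[3])^2
  off <- off[d2 <= eff^2, , drop = FALSE]
  n <- dim(mask)
  out <- array(FALSE, n)
  for (k in seq_len(nrow(off))) {
    sx <- off$dx[k]; sy <- off$dy[k]; sz <- off$dz[k]
    xs <- max(1, 1 + sx):min(n[1], n[1] + sx)
    ys <- max(1, 1 + sy):min(n[2], n[2] + sy)
    zs <- max(1, 1 + sz):min(n[3], n[3] + sz)
    out[xs, ys, zs] <- out[xs, ys, zs] |
      mask[xs - sx, ys - sy, zs - sz]
  }
  out
}

#' Assign materials and densities to a phantom
#'
#' Converts the HU volume to the media map (air / lung / soft tissue /
#' bone) and density via [hu_to_material()], then overrides the GTV voxels
#' with the iodinated filling material and its volume-additive density,
#' regardless of their HU.
#'
#' @param phantom a `voxel_phantom` with HU
#' @param structures a `structure_set` containing a `GTV` mask
#' @param lipiodol filling material from [lipiodol_material()]
#' @param bands HU banding configuration
#' @return the phantom with `materials`, `material_index` and `density`
#'   filled in
#' @export
assign_materials <- function(phantom, structures,
                             lipiodol = lipiodol_material(50),
                             bands = hu_band_defaults()) {
  if (is.null(phantom$hu)) {
    abort("phantom carries no HU volume", class = "kvcert_config_error")
  }
  conv <- hu_to_material(as.numeric(phantom$hu), bands)
  mat_names <- c("air", "lung", "soft_tissue", "cortical_bone")
  idx <- match(conv$material, mat_names)
  density <- conv$density
  materials <- lapply(mat_names, standard_material)
  names(materials) <- mat_names
  gtv <- as.logical(structures$GTV)
  materials$gtv_fill <- lipiodol
  idx[gtv] <- length(materials)
  density[gtv] <- lipiodol$density
  phantom$materials <- materials
  phantom$material_index <- array(idx, dim(phantom$hu))
  phantom$density <- array(density, dim(phantom$hu))
  phantom
}

#' Sample a surrogate clinical tumour HU distribution
#'
#' Draws from a truncated normal on the clinically observed HU interval
#' `[376.2, 1653]` with mean 864.7 HU, emulating the post-embolisation
#' tumour CT-number distribution for pipeline demonstrations and tests.
#'
#' @param n number of samples (>= 1)
#' @param mean_hu,sd_hu parent normal parameters before truncation
#' @param range_hu truncation interval
#' @param seed RNG seed
#' @return numeric vector of HU values
#' @export
sample_patient_gtv_hu <- function(n, mean_hu = 864.7, sd_hu = 320,
                                  range_hu = c(376.2, 1653), seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  plo <- stats::pnorm(range_hu[1], mean_hu, sd_hu)
  phi <- stats::pnorm(range_hu[2], mean_hu, sd_hu)
  u <- runif(n, plo, phi)
  stats::qnorm(u, mean_hu, sd_hu)
}

#' Write / read a phantom and its structures
#'
#' The HU volume is stored as double-precision NIfTI, each mask as an
#' unsigned 8-bit NIfTI, and voxel size, origin, seed and concentration in
#' a JSON sidecar.
#'
#' @param phantom a `voxel_phantom`
#' @param structures a `structure_set`
#' @param dir output directory (created if needed)
#' @return `read_phantom` returns a list with `phantom` and `structures`
#' @export
write_phantom <- function(phantom, structures, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  RNifti::writeNifti(RNifti::asNifti(phantom$hu,
                                     pixdim = rep(phantom$voxel_mm, 3)),
                     file.path(dir, "hu.nii.gz"), datatype = "double")
  for (nm in names(structures)) {
    RNifti::writeNifti(
      RNifti::asNifti(array(as.integer(structures[[nm]]),
                            dim(structures[[nm]])),
                      pixdim = rep(attr(structures, "voxel_mm"), 3)),
      file.path(dir, paste0("mask_", nm, ".nii.gz")), datatype = "uint8")
  }
  sidecar <- list(voxel_mm = phantom$voxel_mm, origin_mm = phantom$origin_mm,
                  seed = phantom$seed,
                  concentration = phantom$params$concentration,
                  masks = names(structures))
  jsonlite::write_json(sidecar, file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "phantom.json"),
                                 simplifyVector = TRUE)
  hu <- array(as.numeric(RNifti::readNifti(file.path(dir, "hu.nii.gz"))),
              dim(RNifti::readNifti(file.path(dir, "hu.nii.gz"))))
  masks <- lapply(sidecar$masks, function(nm) {
    m <- RNifti::readNifti(file.path(dir, paste0("mask_", nm, ".nii.gz")))
    array(as.numeric(m) > 0, dim(m))
  })
  names(masks) <- sidecar$masks
  phantom <- structure(list(
    hu = hu, voxel_mm = sidecar$voxel_mm, origin_mm = sidecar$origin_mm,
    materials = NULL, material_index = NULL, density = NULL,
    params = list(concentration = sidecar$concentration),
    seed = sidecar$seed), class = "voxel_phantom")
  structures <- structure(masks, class = "structure_set",
                          voxel_mm = sidecar$voxel_mm)
  list(phantom = phantom, structures = structures)
}
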