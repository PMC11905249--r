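test_that("structure-set identities hold across seeds and voxel sizes", {
  for (case in list(c(3, 1), c(4.5, 2), c(4, 7))) {
    ab <- build_synthetic_abdomen(abdomen_params(voxel_mm = case[1]),
                                  seed = case[2])
    st <- ab$structures
    expect_true(all(st$GTV[st$GTV] & st$LIVER[st$GTV]))     # GTV in liver
    expect_true(all(st$BODY[st$LIVER]))                     # liver in body
    expect_true(all(st$PTV[st$GTV]))                        # PTV covers GTV
    expect_identical(st$NORMAL_LIVER, st$LIVER & !st$GTV)
    expect_false(any(st$NORMAL_LIVER & st$GTV))
    expect_false(any(st$SPINAL_CORD & (st$LIVER | st$KIDNEY_L |
                                         st$KIDNEY_R)))
    expect_false(any(st$SPINAL_CORD & st$BONE))
  }
})

test_that("voxelised GTV volume matches the analytic sphere", {
  ab <- build_synthetic_abdomen(abdomen_params(voxel_mm = 3), seed = 1)
  vol_cc <- sum(ab$structures$GTV) * 0.3^3
  expect_lt(abs(vol_cc / (4 / 3 * pi * 1.5^3) - 1), 0.05)
})

test_that("GTV HU follows the concentration calibration", {
  p <- abdomen_params(voxel_mm = 3, concentration = 50)
  ab <- build_synthetic_abdomen(p, seed = 3)
  cal <- lipiodol_calibration()
  expected <- suppressWarnings(concentration_to_hu(cal, 50))
  gtv_hu <- ab$phantom$hu[ab$structures$GTV]
  tol <- 3 * p$noise_sd_hu / sqrt(length(gtv_hu))
  expect_lt(abs(mean(gtv_hu) - expected), tol)
})

test_that("margin expansion is an isotropic Euclidean dilation", {
  ab <- build_synthetic_abdomen(abdomen_params(voxel_mm = 3), seed = 1)
  gtv <- ab$structures$GTV
  expect_identical(expand_margin(gtv, 0, 3), gtv)
  # 3 cm sphere + 5 mm margin -> 4 cm sphere, ~33.5 cc
  ptv <- expand_margin(gtv, 5, 3)
  expect_lt(abs(sum(ptv) * 0.027 / (4 / 3 * pi * 2^3) - 1), 0.05)
  # monotone inclusion
  for (m in c(2, 5, 9)) {
    bigger <- expand_margin(gtv, m, 3)
    expect_true(all(bigger[gtv]))
  }
  expect_error(expand_margin(gtv, -1, 3), class = "kvcert_domain_error")
})

test_that("material assignment maps bands and overrides the GTV", {
  ab <- build_synthetic_abdomen(
    abdomen_params(voxel_mm = 4.5, concentration = 50), seed = 1)
  lip <- lipiodol_material(50)
  ph <- assign_materials(ab$phantom, ab$structures, lip)
  st <- ab$structures
  nm <- names(ph$materials)
  # all bone-band HU voxels (outside the GTV) map to bone material
  bone_band <- ph$hu > 120 & !st$GTV
  expect_true(all(nm[ph$material_index[bone_band]] == "cortical_bone"))
  # GTV voxels get the filling material and its density, regardless of HU
  expect_true(all(nm[ph$material_index[st$GTV]] == "gtv_fill"))
  expect_true(all(ph$density[st$GTV] == lip$density))
  expect_equal(lip$density, standard_material("soft_tissue")$density + 0.05)
  # with concentration 0 the GTV behaves as the base soft tissue
  ph0 <- assign_materials(ab$phantom, ab$structures, lipiodol_material(0))
  m0 <- ph0$materials$gtv_fill
  expect_equal(m0$elements, standard_material("soft_tissue")$elements)
})

test_that("clinical tumour HU surrogate has the stated distribution", {
  hu <- sample_patient_gtv_hu(20000, seed = 11)
  expect_true(all(hu >= 376.2 & hu <= 1653))
  # truncated-normal mean oracle via numerical integration
  f <- function(x) stats::dnorm(x, 864.7, 320)
  z <- stats::integrate(f, 376.2, 1653)$value
  m_expect <- stats::integrate(function(x) x * f(x), 376.2, 1653)$value / z
  v_expect <- stats::integrate(function(x) x^2 * f(x), 376.2, 1653)$value /
    z - m_expect^2
  expect_lt(abs(mean(hu) - m_expect), 3 * sqrt(v_expect / length(hu)))
  # converted concentrations stay inside the calibrated range
  conc <- hu_to_concentration(lipiodol_calibration(), hu)
  expect_true(all(conc >= 11.4 & conc <= 49.4))
})

test_that("phantom I/O roundtrip is lossless for HU and masks", {
  ab <- build_synthetic_abdomen(abdomen_params(voxel_mm = 4.5), seed = 5)
  dir <- file.path(tempdir(), "phantom_io")
  write_phantom(ab$phantom, ab$structures, dir)
  back <- read_phantom(dir)
  expect_equal(back$phantom$hu, ab$phantom$hu, tolerance = 0)
  for (nm in names(ab$structures)) {
    expect_identical(back$structures[[nm]],
                     unclass(ab$structures)[[nm]], label = nm)
  }
  unlink(dir, recursive = TRUE)
})

test_that("a tumour outside the liver is rejected", {
  p <- abdomen_params()
  p$gtv_diameter_mm <- 200
  expect_error(build_synthetic_abdomen(p),
               class = "kvcert_geometry_error")
})
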