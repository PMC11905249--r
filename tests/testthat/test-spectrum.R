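test_that("generated spectra respect the tube-potential endpoint", {
  s <- generate_spectrum(120, 0.2)
  expect_true(all(s$energy_keV <= 120))
  expect_true(all(s$fluence >= 0))
  expect_equal(sum(s$fluence), 1, tolerance = 1e-12)
  expect_error(generate_spectrum(30), class = "kvcert_domain_error")
})

test_that("added filtration hardens the beam", {
  mean_e <- function(t) {
    s <- generate_spectrum(120, t)
    sum(s$energy_keV * s$fluence)
  }
  ts <- c(0.05, 0.1, 0.3, 0.6, 1)
  expect_true(all(diff(vapply(ts, mean_e, numeric(1))) > 0))
  hvls <- vapply(ts, function(t) hvl_of_spectrum(generate_spectrum(120, t)),
                 numeric(1))
  expect_true(all(diff(hvls) > 0))
})

test_that("spectrum HVL solves the air-kerma transmission equation", {
  # T(0) = 1 exactly
  s <- generate_spectrum(120, 0.3)
  expect_equal(kvcert:::spectrum_transmission_al(s, 0), 1)
  hvl <- hvl_of_spectrum(s)
  expect_equal(kvcert:::spectrum_transmission_al(s, hvl), 0.5,
               tolerance = 1e-6)
  # monoenergetic closed form: ln 2 / (mu/rho * rho_Al)
  mono <- monoenergetic_spectrum(60)
  expect_equal(hvl_of_spectrum(mono), hvl_from_energy(60), tolerance = 1e-4)
  expect_lt(abs(hvl_of_spectrum(mono) - 9.24), 0.05)
})

test_that("inherent filtration calibrates to the target beam quality", {
  cal <- calibrate_inherent_filtration(9.4)
  expect_lt(abs(cal$achieved_hvl_mm - 9.4), 0.05)
  expect_lt(abs(hvl_of_spectrum(cal$spectrum) - 9.4), 0.05)
  # measured-column target needs less titanium
  cal92 <- calibrate_inherent_filtration(9.2)
  expect_lt(cal92$ti_cm, cal$ti_cm)
  expect_error(calibrate_inherent_filtration(30),
               class = "kvcert_calibration_error")
})

test_that("calibrated beam quality and effective energy compose consistently", {
  cal <- calibrate_inherent_filtration(9.4)
  eff <- effective_energy_from_hvl(cal$achieved_hvl_mm)
  expect_true(abs(eff$energy_keV - 61) <= 1)
})

test_that("off-center ratio is normalised, symmetric and decreasing", {
  geom <- scanner_geometry(inherent_ti_cm = 0.25)
  off <- seq(-12, 12, 2)
  ocr <- off_center_ratio(geom, off)
  expect_equal(ocr$ocr[ocr$offset_cm == 0], 1)
  expect_equal(ocr$ocr, rev(ocr$ocr), tolerance = 1e-12)
  right <- ocr$ocr[ocr$offset_cm >= 0]
  expect_true(all(diff(right) < 0))
  expect_error(off_center_ratio(geom, 40), class = "kvcert_coverage_error")
})

test_that("bowtie profile respects its printed endpoints", {
  bt <- bowtie_filter()
  expect_equal(bowtie_thickness(bt, 0), 0.15)
  expect_equal(bowtie_thickness(bt, bt$fan_half_angle_rad), 2.8)
  ang <- seq(0, bt$fan_half_angle_rad, length.out = 20)
  expect_true(all(diff(bowtie_thickness(bt, ang)) >= 0))
  expect_equal(bowtie_thickness(bt, -ang), bowtie_thickness(bt, ang))
})

test_that("source sampling reproduces the filtered spectrum", {
  geom <- scanner_geometry(inherent_ti_cm = 0.25, field_cm = c(4, 4))
  s <- generate_spectrum(120, 0.25)
  ph <- sample_source_photon(2e4, geom, s, seed = 42)
  expect_true(all(ph$energy_keV <= 120))
  expect_true(all(abs(sqrt(ph$ux^2 + ph$uy^2 + ph$uz^2) - 1) < 1e-12))
  # chi-square against the central-axis bowtie-filtered spectrum
  f <- kvcert:::spectrum_at_angle(s, geom$bowtie, 0)
  edges <- attr(s, "bin_edges")
  counts <- table(cut(ph$energy_keV, edges))
  keep <- f * nrow(ph) >= 5
  chi <- sum((as.numeric(counts)[keep] - nrow(ph) * f[keep])^2 /
               (nrow(ph) * f[keep]))
  p <- stats::pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("a point aperture degenerates to a single direction", {
  geom <- scanner_geometry(inherent_ti_cm = 0.25, field_cm = c(1e-9, 1e-9))
  ph <- sample_source_photon(100, geom, generate_spectrum(120, 0.25),
                             seed = 1)
  expect_lt(diff(range(ph$ux)), 1e-9)
  expect_lt(diff(range(ph$uz)), 1e-9)
})

test_that("spectrum TSV roundtrip preserves the fluence", {
  s <- generate_spectrum(120, 0.3)
  path <- tempfile(fileext = ".tsv")
  write_spectrum(s, path)
  s2 <- read_spectrum(path)
  expect_equal(s2$fluence, s$fluence, tolerance = 1e-6)
  expect_equal(s2$energy_keV, s$energy_keV)
})
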