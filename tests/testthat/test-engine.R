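test_that("energy is conserved in every batch", {
  case <- coarse_case(50)
  cfg <- transport_config(5e4, 5, seed = 21)
  g <- run_simulation(case$phantom, case$beams, cfg)
  a <- g$audit
  rel <- abs(rowSums(a[, 2:4]) - a[, 1]) / a[, 1]
  expect_true(all(rel < 1e-6))
  # deposited energy never exceeds emitted energy
  expect_true(all(a[, 2] <= a[, 1]))
})

test_that("identical seeds give bitwise-identical dose grids", {
  case <- coarse_case(50)
  cfg <- transport_config(2e4, 4, seed = 33)
  g1 <- run_simulation(case$phantom, case$beams, cfg)
  g2 <- run_simulation(case$phantom, case$beams, cfg)
  expect_identical(g1$edep_sum, g2$edep_sum)
  expect_identical(g1$audit, g2$audit)
})

test_that("a beam aimed outside the phantom deposits nothing", {
  ph <- water_slab(5, 10, lateral_cm = 4, n_lateral = 2)
  beam <- beam_spec(c(0, 25, 1000), c(0, 1, 0), 1, 1, parallel = TRUE)
  g <- run_simulation(ph, list(beam), transport_config(1e4, 2, seed = 1),
                      spectrum = monoenergetic_spectrum(60))
  expect_true(all(g$edep_sum == 0))
  expect_equal(sum(g$audit[, 3]), sum(g$audit[, 1]))
})

test_that("primary-only depth dose follows Beer-Lambert", {
  ph <- water_slab(10, 50)
  cfg <- transport_config(4e5, 10, seed = 7, primary_only = TRUE)
  g <- run_simulation(ph, list(full_face_beam()), cfg,
                      spectrum = monoenergetic_spectrum(60))
  dd <- apply(g$edep_sum, 2, sum)
  z <- (seq_len(50) - 0.5) * 0.2
  mu_fit <- -stats::coef(stats::lm(log(dd) ~ z))[[2]]
  mu <- mixture_mu("water", 60, "total")
  # per-depth-bin SE translates into a slope SE well under 2%
  expect_lt(abs(mu_fit / mu - 1), 0.02)
})

test_that("entrance dose per unit energy fluence equals mu_en/rho", {
  ph <- water_slab(0.2, 2)
  cfg <- transport_config(1e6, 10, seed = 3, primary_only = TRUE)
  g <- run_simulation(ph, list(full_face_beam()), cfg,
                      spectrum = monoenergetic_spectrum(60))
  psi <- g$histories * 60 / 400  # keV / cm^2 over the 20 x 20 cm face
  mass_g <- prod(ph$voxel_mm / 10) * 1.0
  d <- sum(g$edep_sum[, 1, ]) / (4 * mass_g)
  mu <- mixture_mu("water", 60, "total")
  mu_en <- mixture_mu("water", 60, "mu_en")
  # expected entrance-layer average includes in-layer attenuation
  expected <- psi * mu_en * (1 - exp(-mu * 0.1)) / (mu * 0.1)
  se <- expected / sqrt(sum(g$edep_sum[, 1, ] > 0))  # ~1/sqrt(interactions)
  u <- estimate_uncertainty(g, min_density = 0.5)
  se_batch <- expected * max(u$rel_se[, 1, ][g$edep_sum[, 1, ] > 0])
  expect_lt(abs(d - expected), 2 * max(se, se_batch))
})

test_that("Klein-Nishina sampler matches the analytic kernel", {
  for (E in c(30, 60, 100)) {
    s <- sample_compton(2e4, E, seed = 5)
    a <- E / 511
    # exact kinematic limits
    expect_true(all(s$scattered_keV <= E + 1e-9))
    expect_true(all(s$scattered_keV >= E / (1 + 2 * a) - 1e-9))
    # quadrature CDF of cos(theta)
    mu <- seq(-1, 1, length.out = 4001)
    k <- 1 / (1 + a * (1 - mu))
    pdf <- k^2 * (k + 1 / k - (1 - mu^2))
    cdf <- cumsum(pdf) / sum(pdf)
    ks <- suppressWarnings(
      stats::ks.test(s$cos_theta,
                     function(q) approx(mu, cdf, xout = q, rule = 2)$y))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("Compton kinematics honour the closed-form limits", {
  # the sampled pairs satisfy the Compton relation exactly, so the
  # forward limit E'(0) = E and backscatter limit E/(1 + 2E/511) bound them
  s <- sample_compton(5e3, 60, seed = 2)
  a <- 60 / 511
  expect_equal(s$scattered_keV, 60 / (1 + a * (1 - s$cos_theta)),
               tolerance = 1e-12)
  expect_lte(max(s$scattered_keV), 60)
  expect_gte(min(s$scattered_keV), 60 / (1 + 2 * a))
})

test_that("interaction branching follows the partial cross sections", {
  p <- interaction_probabilities("cortical_bone", 20)
  expect_equal(sum(p$probability), 1, tolerance = 1e-12)
  expect_gt(p$probability[p$channel == "photoelectric"], 0.5)
  # chi-square of sampled branches against the table ratios
  draws <- sample_interaction(1e5, "water", 60, seed = 8)
  pw <- interaction_probabilities("water", 60)
  obs <- table(factor(draws, levels = pw$channel))
  chi <- sum((as.numeric(obs) - 1e5 * pw$probability)^2 /
               (1e5 * pw$probability))
  expect_gt(stats::pchisq(chi, df = 2, lower.tail = FALSE), 0.01)
})

test_that("K fluorescence only triggers above the edge and exports energy", {
  # iodinated slab, monoenergetic beams below / above the iodine K edge
  lip <- lipiodol_material(400, base = "water")
  ph <- kvcert:::slab_phantom(list(list(material = lip, thickness_cm = 2)),
                              lateral_cm = 10, n_depth = 4, n_lateral = 2)
  beam <- beam_spec(c(0, 0, 0), c(0, 1, 0), 5, 5, parallel = TRUE)
  dep_fraction <- function(E, fluor) {
    cfg <- transport_config(5e4, 5, seed = 9, fluorescence = fluor)
    g <- run_simulation(ph, list(beam), cfg,
                        spectrum = monoenergetic_spectrum(E))
    a <- colSums(g$audit)
    a[2] / a[1]
  }
  # below the edge (30 keV): fluorescence setting changes nothing
  expect_equal(dep_fraction(30, TRUE), dep_fraction(30, FALSE),
               tolerance = 1e-12)
  # above the edge (40 keV): K-alpha escape reduces local deposition
  expect_lt(dep_fraction(40, TRUE), dep_fraction(40, FALSE))
})

test_that("batch uncertainty matches a hand-computed toy case and scales", {
  case <- coarse_case(50)
  g1 <- run_simulation(case$phantom, case$beams,
                       transport_config(4e4, 8, seed = 13))
  g2 <- run_simulation(case$phantom, case$beams,
                       transport_config(4e5, 8, seed = 13))
  u1 <- estimate_uncertainty(g1)$max_rel_se_hot
  u2 <- estimate_uncertainty(g2)$max_rel_se_hot
  # 10x histories: relative SE should drop roughly as 1/sqrt(10)
  expect_lt(u2, u1)
  expect_lt(u2 / u1, 3 / sqrt(10))
  # hand-computed two-batch grid
  g <- g1
  g$n_batches <- 2
  g$edep_sum <- array(c(3, 0), c(2, 1, 1))       # batches 1 + 2, 0 + 0
  g$edep_sumsq <- array(c(5, 0), c(2, 1, 1))     # 1^2 + 2^2
  g$density <- array(1, c(2, 1, 1))
  u <- estimate_uncertainty(g, min_density = 0)
  # batch values 1 and 2: var = 0.5, SE(total) = sqrt(2 * 0.5) = 1
  expect_equal(u$rel_se[1, 1, 1], 1 / 3)
  expect_error({g$n_batches <- 1; estimate_uncertainty(g)},
               class = "kvcert_statistics_error")
})

test_that("uncertainty-targeted runs extend until the target is met", {
  case <- coarse_case(50)
  cfg <- transport_config(2e5, 5, seed = 17, uncertainty_target = 0.2,
                          max_rounds = 20)
  g <- run_simulation(case$phantom, case$beams, cfg)
  expect_lte(estimate_uncertainty(g)$max_rel_se_hot, 0.2)
  expect_gte(g$n_batches, 5)
})
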