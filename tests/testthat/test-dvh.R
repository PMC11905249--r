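# brute-force oracles: direct definitions on the sorted masked doses
oracle_dx_pct <- function(d, pct) {
  d <- sort(d, decreasing = TRUE)
  n <- length(d)
  k <- min(max(pct / 100 * n + 0.5, 1), n)
  lo <- floor(k); hi <- ceiling(k)
  d[lo] + (k - lo) * (d[hi] - d[lo])
}
oracle_dcc <- function(d, cc, vox_cc) {
  d <- sort(d, decreasing = TRUE)
  d[ceiling(cc / vox_cc - 1e-9)]
}
oracle_vx <- function(d, thr) 100 * mean(d >= thr)

test_that("uniform dose collapses the DVH to a step", {
  dose <- array(7, c(4, 4, 4))
  mask <- array(TRUE, c(4, 4, 4))
  curve <- cumulative_dvh(dose, mask, bin_gy = 0.5)
  expect_equal(curve$volume_fraction[curve$dose_gy == 0], 1)
  expect_true(all(curve$volume_fraction[curve$dose_gy <= 7] == 1))
  expect_true(all(curve$volume_fraction[curve$dose_gy > 7] == 0))
  for (x in c(2, 50, 98)) {
    expect_equal(dose_at_volume(dose, mask, x), 7)
  }
})

test_that("percentile interpolation follows the midpoint convention", {
  dose <- array(as.numeric(1:100), c(100, 1, 1))
  mask <- array(TRUE, c(100, 1, 1))
  expect_equal(dose_at_volume(dose, mask, 50), 50.5)
  expect_equal(dose_at_volume(dose, mask, 2), 98.5)
  expect_equal(dose_at_volume(dose, mask, 100), 1)
})

test_that("a single 0.1 cc hotspot voxel defines D0.1cc exactly", {
  vox_mm <- 0.1^(1 / 3) * 10  # 0.1 cc voxels: 4.6416 mm isotropic
  dose <- array(5, c(5, 5, 5))
  dose[3, 3, 3] <- 60
  mask <- array(TRUE, c(5, 5, 5))
  expect_equal(dose_at_volume(dose, mask, volume_cc = 0.1,
                              voxel_mm = vox_mm), 60)
  expect_error(dose_at_volume(dose, mask, volume_cc = 1e9,
                              voxel_mm = vox_mm),
               class = "kvcert_domain_error")
})

test_that("volume at dose follows the counting definition", {
  dose <- array(c(rep(30, 50), rep(10, 50)), c(100, 1, 1))
  mask <- array(TRUE, c(100, 1, 1))
  expect_equal(volume_at_dose(dose, mask, 20), 50)
  expect_equal(volume_at_dose(dose, mask, 0), 100)
  expect_equal(volume_at_dose(dose, mask, 31), 0)
  expect_error(volume_at_dose(dose, array(FALSE, c(100, 1, 1)), 5),
               class = "kvcert_structure_error")
})

test_that("metrics match the brute-force oracle on random grids", {
  set.seed(99)
  vox_mm <- 3
  vox_cc <- 0.027
  for (i in 1:1000) {
    n <- sample(20:120, 1)
    d <- stats::rgamma(n, shape = 2, scale = 10)
    dose <- array(d, c(n, 1, 1))
    mask <- array(TRUE, c(n, 1, 1))
    pct <- stats::runif(1, 1, 99)
    expect_equal(dose_at_volume(dose, mask, pct), oracle_dx_pct(d, pct),
                 tolerance = 1e-9)
    thr <- stats::runif(1, 0, 40)
    expect_equal(volume_at_dose(dose, mask, thr), oracle_vx(d, thr),
                 tolerance = 1e-9)
    expect_equal(dose_at_volume(dose, mask, volume_cc = 0.1,
                                voxel_mm = vox_mm),
                 oracle_dcc(d, 0.1, vox_cc), tolerance = 1e-9)
  }
})

test_that("binned DVH curve equals the direct sort-based computation", {
  set.seed(7)
  d <- stats::runif(100, 0, 20)
  dose <- array(d, c(100, 1, 1))
  mask <- array(TRUE, c(100, 1, 1))
  curve <- cumulative_dvh(dose, mask, bin_gy = 0.5)
  direct <- vapply(curve$dose_gy, function(e) mean(d >= e), numeric(1))
  expect_equal(curve$volume_fraction, direct, tolerance = 1e-12)
})

test_that("metrics are reorder-invariant and Dmean is the exact mean", {
  set.seed(31)
  d <- stats::runif(200, 0, 50)
  dose1 <- array(d, c(200, 1, 1))
  dose2 <- array(sample(d), c(200, 1, 1))
  mask <- array(TRUE, c(200, 1, 1))
  m1 <- plan_metrics(dose1, list(S = mask), 3)
  m2 <- plan_metrics(dose2, list(S = mask), 3)
  expect_equal(m1$value, m2$value, tolerance = 1e-12)
  expect_equal(m1$value[m1$metric == "Dmean"], mean(d), tolerance = 1e-12)
  # ordering invariants
  v <- setNames(m1$value, m1$metric)
  expect_true(v[["D98%"]] <= v[["D50%"]] && v[["D50%"]] <= v[["D2%"]])
  expect_gte(v[["V5Gy"]], v[["V20Gy"]])
})

test_that("dose_at_volume and volume_at_dose are mutually consistent", {
  set.seed(5)
  d <- stats::rgamma(500, 3, 0.1)
  dose <- array(d, c(500, 1, 1))
  mask <- array(TRUE, c(500, 1, 1))
  for (v in c(5, 20, 50, 80, 95)) {
    dx <- dose_at_volume(dose, mask, v)
    expect_gte(volume_at_dose(dose, mask, dx) + 100 / 500, v)
  }
})

test_that("constraint checking follows the boundary convention", {
  metrics <- tibble::tibble(
    structure = c("A", "A", "B"), metric = c("Dmean", "V20Gy", "D0.1cc"),
    value = c(13, 25, 18), unit = c("Gy", "%", "Gy"))
  empty <- check_constraints(metrics, tibble::tibble(
    structure = character(), metric = character(), limit = numeric(),
    direction = character()))
  expect_true(attr(empty, "all_pass"))
  cons <- tibble::tibble(structure = c("A", "A", "B"),
                         metric = c("Dmean", "V20Gy", "D0.1cc"),
                         limit = c(13, 20, 20), direction = "le")
  rep <- check_constraints(metrics, cons)
  expect_equal(rep$pass, c(TRUE, FALSE, TRUE))  # exactly one violation
  expect_false(attr(rep, "all_pass"))
  cons_bad <- tibble::tibble(structure = "C", metric = "Dmean", limit = 1,
                             direction = "le")
  expect_error(check_constraints(metrics, cons_bad),
               class = "kvcert_config_error")
})
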