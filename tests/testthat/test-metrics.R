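test_that("suv_max matches an exhaustive voxel scan", {
  set.seed(42)
  g <- voxel_grid(array(runif(20^3, 0, 10), c(20, 20, 20)), 2.5)
  voi <- sphere_voi(c(25, 25, 25), 20)
  expect_equal(suv_max_in_voi(g, voi),
               max(brute_voi_values(g, c(25, 25, 25), 10)))
  # uniform grid: any VOI returns the constant
  gu <- voxel_grid(array(3.7, c(10, 10, 10)), 3)
  expect_equal(suv_max_in_voi(gu, sphere_voi(c(15, 15, 15), 12)), 3.7)
  expect_error(suv_max_in_voi(gu, sphere_voi(c(500, 500, 500), 4)),
               "no voxel centers")
})

test_that("suv_peak equals the brute-force sphere-mean maximum", {
  # spike s in uniform background b: the best sphere covers the spike,
  # mean = (s + (n-1) b) / n with n the sphere's voxel count
  g <- voxel_grid(array(1, c(15, 15, 15)), 3)
  g$values[8, 8, 8] <- 5  # voxel center at (22.5, 22.5, 22.5)
  ctr <- c(22.5, 22.5, 22.5)
  n <- length(brute_voi_values(g, ctr, 6))
  expect_equal(suv_peak_in_voi(g, sphere_voi(ctr, 9)),
               (5 + (n - 1) * 1) / n)
  # uniform grid returns the constant
  gu <- voxel_grid(array(2.2, c(15, 15, 15)), 3)
  expect_equal(suv_peak_in_voi(gu, sphere_voi(ctr, 9)), 2.2)
  # shift equivariance: adding a constant moves the peak by that constant
  g2 <- g; g2$values <- g2$values + 1.3
  expect_equal(suv_peak_in_voi(g2, sphere_voi(ctr, 9)),
               suv_peak_in_voi(g, sphere_voi(ctr, 9)) + 1.3)
  # exhaustive-search peak can never exceed the VOI maximum here
  expect_lte(suv_peak_in_voi(g, sphere_voi(ctr, 9)),
             suv_max_in_voi(g, sphere_voi(ctr, 9)))
})

test_that("lean body mass follows the James formula with clamping", {
  expect_equal(lean_body_mass(70, 170, "male"),
               1.10 * 70 - 128 * (70 / 170)^2, tolerance = 1e-12)
  expect_equal(lean_body_mass(70, 170, "male"), 55.2976, tolerance = 1e-4)
  expect_equal(lean_body_mass(60, 160, "female"),
               1.07 * 60 - 148 * (60 / 160)^2, tolerance = 1e-12)
  # very tall light person: formula exceeds weight, clamp to weight
  # (1.10 * 30 - 128 * (30/200)^2 = 30.12 > 30)
  expect_equal(lean_body_mass(30, 200, "male"), 30)
  expect_error(lean_body_mass(200, 100, "male"), "non-physiologic")
})

test_that("suv_to_sul is linear, bounded by suv, and exact on hand values", {
  expect_equal(suv_to_sul(0, 70, 170, "male"), 0)
  lbm <- lean_body_mass(70, 170, "male")
  expect_equal(suv_to_sul(10, 70, 170, "male"), 10 * lbm / 70)
  expect_equal(suv_to_sul(6, 70, 170, "male"),
               2 * suv_to_sul(3, 70, 170, "male"))
  expect_lte(suv_to_sul(8.4, 55, 180, "female"), 8.4)
  # clamped LBM = W implies SUL = SUV
  expect_equal(suv_to_sul(5, 30, 200, "male"), 5)
})

test_that("mtv_and_tlg matches exhaustive threshold counting", {
  set.seed(7)
  g <- voxel_grid(array(runif(15^3, 0, 1), c(15, 15, 15)), 2)
  ctr <- c(15, 15, 15)
  # plant a compact hot blob so the 40% component is non-trivial
  g$values[6:9, 6:9, 6:9] <- runif(64, 4, 10)
  voi <- sphere_voi(ctr, 22)
  res <- mtv_and_tlg(g, voi)
  vals <- brute_voi_values(g, ctr, 11)
  smax <- max(vals)
  # blob is a single connected block: component = all above-threshold
  # voxels in it (background stays below 0.4 * smax >= 1.6)
  n_above <- sum(vals >= 0.4 * smax)
  expect_equal(res$mtv_ml, n_above * 8 / 1000)
  expect_equal(res$tlg, res$suv_mean * res$mtv_ml)
  expect_gte(res$suv_mean, 0.4 * smax)
  expect_lte(res$suv_mean, smax)
})

test_that("mtv isocontour is restricted to the component holding the max", {
  g <- voxel_grid(array(0, c(20, 20, 20)), 2)
  g$values[5:7, 5:7, 5:7] <- 10       # main lesion
  g$values[15:16, 15:16, 15:16] <- 9  # disconnected hot speckle
  voi <- sphere_voi(c(20, 20, 20), 40)
  res <- mtv_and_tlg(g, voi)
  expect_equal(res$mtv_ml, 27 * 8 / 1000)  # speckle excluded
  expect_equal(res$suv_mean, 10)
})

test_that("uniform lesion on zero background gives exact MTV and TLG", {
  g <- voxel_grid(array(0, c(16, 16, 16)), 2)
  idx <- voi_voxels(g, sphere_voi(c(16, 16, 16), 16))
  g$values[idx] <- 6
  res <- mtv_and_tlg(g, sphere_voi(c(16, 16, 16), 20))
  expect_equal(res$mtv_ml, length(idx) * 8 / 1000)
  expect_equal(res$suv_mean, 6)
  expect_equal(res$tlg, 6 * length(idx) * 8 / 1000)
  expect_warning(res0 <- mtv_and_tlg(
    voxel_grid(array(0, c(8, 8, 8)), 3), sphere_voi(c(12, 12, 12), 12)),
    "MTV and TLG set to 0")
  expect_equal(res0$tlg, 0)
})

test_that("liver reference reproduces two-pass mean/SD and thresholds", {
  g <- voxel_grid(array(2.0, c(20, 20, 20)), 3)
  lr <- liver_reference(g, sphere_voi(c(30, 30, 30), 30))
  expect_equal(lr$sul_mean, 2.0)
  expect_equal(lr$sul_sd, 0)
  expect_equal(lr$measurability_floor, 3.0)
  set.seed(11)
  g$values <- array(rnorm(8000, 2, 0.2), c(20, 20, 20))
  voi <- sphere_voi(c(30, 30, 30), 30)
  lr2 <- liver_reference(g, voi)
  vals <- brute_voi_values(g, c(30, 30, 30), 15)
  expect_equal(lr2$sul_mean, sum(vals) / length(vals))
  expect_equal(lr2$sul_sd,
               sqrt(sum((vals - mean(vals))^2) / (length(vals) - 1)))
  expect_equal(lr2$sul_mean_plus_2sd, lr2$sul_mean + 2 * lr2$sul_sd)
  expect_error(liver_reference(g, sphere_voi(c(500, 0, 0), 30)),
               "liver sphere")
})

test_that("measure_scan composes per-lesion metrics additively", {
  g <- voxel_grid(array(0.5, c(30, 30, 30)), 3)
  i1 <- voi_voxels(g, sphere_voi(c(20, 20, 20), 14))
  i2 <- voi_voxels(g, sphere_voi(c(70, 70, 70), 14))
  g$values[i1] <- 8; g$values[i2] <- 5
  vois <- list(a = sphere_voi(c(20, 20, 20), 18),
               b = sphere_voi(c(70, 70, 70), 18))
  m <- measure_scan(g, vois, sphere_voi(c(45, 45, 45), 30),
                    organ_labels = c("lung", "bone"))
  expect_equal(nrow(m$lesions), 2)
  expect_equal(m$lesions$suv_max, c(8, 5))
  expect_true(all(m$lesions$suv_peak <= m$lesions$suv_max))
  # per-lesion TLG agrees with an independent single-lesion computation,
  # so the whole-body sum is additive over disjoint lesions
  expect_equal(m$lesions$tlg[1], mtv_and_tlg(g, vois$a)$tlg)
  expect_equal(m$lesions$tlg[2], mtv_and_tlg(g, vois$b)$tlg)
  # zero lesions: empty frame, liver reference still present
  m0 <- measure_scan(g, list(), sphere_voi(c(45, 45, 45), 30))
  expect_equal(nrow(m0$lesions), 0)
  expect_s3_class(m0$liver, "liver_reference")
})

test_that("worked-case MTV x SUV_mean product is consistent with TLG", {
  # single lung lesion measured at MTV 2.22 mL, SUV_mean 4.50: the TLG
  # definition gives 9.99, matching the recorded 10.01 at input rounding
  expect_equal(2.22 * 4.50, 10.01, tolerance = 0.01)
})
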