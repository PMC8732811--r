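test_that("a lesion-free noiseless phantom is background plus liver plateau", {
  spec <- phantom_spec(grid_shape = c(24, 24, 24), voxel_size_mm = 3,
                       background_suv = 1.0,
                       liver_center_mm = c(36, 36, 36), liver_radius_mm = 15,
                       liver_mean_suv = 2.2, liver_sd_suv = 0,
                       noise_sd = 0, seed = 1)
  ph <- generate_phantom(spec)
  liv_idx <- voi_voxels(ph$grid, sphere_voi(c(36, 36, 36), 30))
  expect_true(all(ph$grid$values[liv_idx] == 2.2))
  outside <- setdiff(seq_along(ph$grid$values),
                     voi_voxels(ph$grid, sphere_voi(c(36, 36, 36), 31)))
  expect_true(all(ph$grid$values[outside] == 1.0))
  expect_length(ph$lesion_vois, 0)
})

test_that("an unblurred noiseless lesion renders its peak exactly", {
  # center (31.5, ...) is a voxel center for 3 mm spacing (origin 1.5)
  les <- data.frame(cx = 31.5, cy = 31.5, cz = 31.5, radius_mm = 9,
                    peak_suv = 10, organ = "lung")
  spec <- phantom_spec(grid_shape = c(30, 30, 30), voxel_size_mm = 3,
                       lesions = les, liver_center_mm = c(70, 70, 70),
                       liver_radius_mm = 15, noise_sd = 0, seed = 2)
  ph <- generate_phantom(spec)
  expect_equal(suv_max_in_voi(ph$grid, ph$lesion_vois[[1]]), 10)
})

test_that("phantom generation is deterministic under a fixed seed", {
  les <- data.frame(cx = 30, cy = 30, cz = 30, radius_mm = 9, peak_suv = 8,
                    organ = "lung")
  spec <- phantom_spec(grid_shape = c(24, 24, 24), voxel_size_mm = 3,
                       lesions = les, liver_center_mm = c(55, 55, 55),
                       liver_radius_mm = 12, scanner_fwhm_mm = 5.8,
                       noise_sd = 0.1, seed = 99)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$grid$values, b$grid$values)
})

test_that("invalid phantom geometry is rejected with diagnostics", {
  les_out <- data.frame(cx = 2, cy = 30, cz = 30, radius_mm = 9, peak_suv = 8,
                        organ = "lung")
  expect_error(phantom_spec(grid_shape = c(24, 24, 24), voxel_size_mm = 3,
                            lesions = les_out,
                            liver_center_mm = c(55, 55, 55),
                            liver_radius_mm = 12),
               "outside the grid")
  les_liver <- data.frame(cx = 50, cy = 50, cz = 50, radius_mm = 9,
                          peak_suv = 8, organ = "lung")
  expect_error(phantom_spec(grid_shape = c(24, 24, 24), voxel_size_mm = 3,
                            lesions = les_liver,
                            liver_center_mm = c(55, 55, 55),
                            liver_radius_mm = 12),
               "overlap the liver")
  les_cold <- data.frame(cx = 30, cy = 30, cz = 30, radius_mm = 9,
                         peak_suv = 0.5, organ = "lung")
  expect_error(phantom_spec(grid_shape = c(24, 24, 24), voxel_size_mm = 3,
                            lesions = les_cold,
                            liver_center_mm = c(55, 55, 55),
                            liver_radius_mm = 12),
               "must exceed the background")
})

test_that("follow-up specs implement the response scenarios", {
  les <- data.frame(cx = 30, cy = 30, cz = 30, radius_mm = 9, peak_suv = 4,
                    organ = "lung")
  base <- phantom_spec(grid_shape = c(30, 30, 30), voxel_size_mm = 3,
                       lesions = les, liver_center_mm = c(70, 70, 70),
                       liver_radius_mm = 15, seed = 5)
  # complete resolution empties the lesion list
  fu <- generate_followup(base, scenario_spec("resolution"))
  expect_equal(nrow(fu$lesions), 0)
  # identity scenario reproduces the baseline spec
  fu1 <- generate_followup(base, scenario_spec("stable", factor = 1))
  expect_equal(fu1, base)
  # growth factor 1.5 on peak 4 over background 1: contrast 3 -> 4.5,
  # peak 5.5; the downstream SUV change is +50% of contrast by construction
  fu2 <- generate_followup(base, scenario_spec("growth", factor = 1.5))
  expect_equal(fu2$lesions$peak_suv, 1 + 1.5 * (4 - 1))
  # new-lesion scenario appends lesions in organs absent at baseline
  fu3 <- generate_followup(base, scenario_spec("new_lesion_only",
                                               n_new_lesions = 2))
  expect_equal(nrow(fu3$lesions), 3)
  expect_false(any(fu3$lesions$organ[2:3] %in% les$organ))
  expect_error(scenario_spec("growth", factor = -1), "factor")
  expect_error(scenario_spec("stable", n_new_lesions = 1), "new lesions")
})
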