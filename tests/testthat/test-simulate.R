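tpl_grid <- grid_spec(c(60, 60, 31), c(1, 1, 2))
tpl_centre <- tpl_grid$origin + (tpl_grid$shape - 1) * tpl_grid$spacing / 2

test_that("zero template gives a zero image; negatives are rejected", {
  tpl <- uptake_template(tpl_grid, array(0, tpl_grid$shape),
                         binary_mask(array(FALSE, tpl_grid$shape), tpl_grid))
  cfg <- scanner_config(default_pet_grid(tpl_grid), noiseless = TRUE)
  expect_true(all(simulate_pet(tpl, cfg)$values == 0))
  expect_error(uptake_template(tpl_grid, array(-1, tpl_grid$shape),
                               tpl$lesion_mask), ">= 0")
})

test_that("a uniform template stays uniform in the interior after blurring", {
  tpl <- uptake_template(tpl_grid, array(2.5, tpl_grid$shape),
                         binary_mask(array(FALSE, tpl_grid$shape), tpl_grid))
  img <- simulate_pet(tpl, scanner_config(default_pet_grid(tpl_grid),
                                          noiseless = TRUE))
  d <- img$grid$shape
  interior <- img$values[8:(d[1] - 7), 8:(d[2] - 7), 6:(d[3] - 5)]
  expect_lt(max(abs(interior - 2.5)) / 2.5, 1e-6)
})

test_that("a point source blurs to the configured FWHM within one PET voxel", {
  vals <- array(0, tpl_grid$shape)
  ctr_idx <- world_to_index(tpl_grid, tpl_centre)
  vals[ctr_idx[1], ctr_idx[2], ctr_idx[3]] <- 1000
  tpl <- uptake_template(tpl_grid, vals,
                         binary_mask(array(FALSE, tpl_grid$shape), tpl_grid))
  pg <- default_pet_grid(tpl_grid)
  img <- simulate_pet(tpl, scanner_config(pg, psf_fwhm_mm = 6.4,
                                          noiseless = TRUE))
  pk <- arrayInd(which.max(img$values), pg$shape)
  prof <- img$values[, pk[2], pk[3]]
  half <- max(prof) / 2
  above <- range(which(prof >= half))
  # linear interpolation of the half-maximum crossings
  left <- above[1] - (prof[above[1]] - half) /
    (prof[above[1]] - prof[above[1] - 1])
  right <- above[2] + (prof[above[2]] - half) /
    (prof[above[2]] - prof[above[2] + 1])
  fwhm_mm <- (right - left) * pg$spacing[1]
  expect_lt(abs(fwhm_mm - 6.4), pg$spacing[1])
})

test_that("noiseless simulation conserves integrated activity to 0.1%", {
  vals <- array(0, tpl_grid$shape)
  ctr_idx <- world_to_index(tpl_grid, tpl_centre)
  vals[(ctr_idx[1] - 6):(ctr_idx[1] + 6),
       (ctr_idx[2] - 6):(ctr_idx[2] + 6),
       (ctr_idx[3] - 3):(ctr_idx[3] + 3)] <- 3
  tpl <- uptake_template(tpl_grid, vals,
                         binary_mask(array(FALSE, tpl_grid$shape), tpl_grid))
  pg <- default_pet_grid(tpl_grid)
  img <- simulate_pet(tpl, scanner_config(pg, noiseless = TRUE))
  act_in <- sum(vals) * voxel_volume(tpl_grid)
  act_out <- sum(img$values) * voxel_volume(pg)
  expect_lt(abs(act_out - act_in) / act_in, 1e-3)
})

test_that("Poisson noise is seed-deterministic and unbiased", {
  tpl <- make_lesion_template(
    make_background(tpl_grid),
    lesion_spec("sphere", 17, "homogeneous", tbr = 4, centre = tpl_centre))
  cfg1 <- scanner_config(default_pet_grid(tpl_grid), noise_seed = 7)
  a <- simulate_pet(tpl, cfg1)
  b <- simulate_pet(tpl, cfg1)
  expect_identical(a$values, b$values)
  cfg2 <- scanner_config(default_pet_grid(tpl_grid), noise_seed = 8)
  expect_false(identical(a$values, simulate_pet(tpl, cfg2)$values))
  noiseless <- simulate_pet(tpl, scanner_config(default_pet_grid(tpl_grid),
                                                noiseless = TRUE))
  expect_lt(abs(mean(a$values) - mean(noiseless$values)) /
              mean(noiseless$values), 0.01)
})

test_that("resampling between identical grids is the identity", {
  vals <- array(stats::runif(prod(tpl_grid$shape)), tpl_grid$shape)
  expect_identical(resample_volume(vals, tpl_grid, tpl_grid), vals)
})

test_that("ground truth extraction matches the analytic sphere volume", {
  tpl <- make_lesion_template(
    grid_centre <- make_background(grid_spec(c(86, 86, 43), c(1, 1, 2))),
    lesion_spec("sphere", 38, "homogeneous", tbr = 4,
                centre = c(42.5, 42.5, 42)))
  pg <- default_pet_grid(tpl$grid)
  gt <- extract_ground_truth(tpl, pg)
  expect_lt(abs(mask_volume_ml(gt) - 28.73) / 28.73, 0.05)
  # identity grid: bit-identical mask
  same <- extract_ground_truth(tpl, tpl$grid)
  expect_identical(same$voxels, tpl$lesion_mask$voxels)
  # empty lesion errors
  bg_only <- make_background(tpl$grid)
  expect_error(extract_ground_truth(bg_only, pg), "empty")
})
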