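test_that("the seed finder lands on hot voxels, ties to the lowest index", {
  g <- grid_spec(c(7, 7, 7), c(2.73, 2.73, 3.27))
  v <- array(1, g$shape); v[4, 4, 4] <- 9
  expect_equal(find_seed(pet_image(v, g)), c(4L, 4L, 4L))
  v2 <- array(1, g$shape); v2[2, 2, 2] <- 9; v2[6, 6, 6] <- 9
  expect_equal(find_seed(pet_image(v2, g)), c(2L, 2L, 2L))
  expect_error(find_seed(pet_image(array(1, g$shape), g)), "constant")
})

test_that("the seed lies inside the true lesion in >= 95% of noisy replicates", {
  entry <- list(id = "S3", battery = "sphere",
                spec = lesion_spec("sphere", 17, "two_level", tbr = 4))
  tpl <- ssphantom:::build_lesion_template(entry)
  pg <- default_pet_grid(tpl$grid)
  noiseless <- simulate_pet(tpl, scanner_config(pg, noiseless = TRUE))
  truth <- extract_ground_truth(tpl, pg)
  hits <- 0L
  n_rep <- 50L
  for (seed in seq_len(n_rep)) {
    roi <- crop_roi(apply_counting_noise(noiseless, 500, seed), truth)
    s <- find_seed(roi$image)
    hits <- hits + roi$truth$voxels[s[1], s[2], s[3]]
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("the background estimate reads the ROI shell", {
  g <- grid_spec(c(9, 9, 7), c(2.73, 2.73, 3.27))
  expect_equal(estimate_background(pet_image(array(2.2, g$shape), g)), 2.2)
  v <- array(1, g$shape); v[4:6, 4:6, 3:5] <- 8   # lesion clear of the shell
  expect_equal(estimate_background(pet_image(v, g)), 1)
  g2 <- grid_spec(c(2, 5, 5), c(2.73, 2.73, 3.27))
  expect_error(estimate_background(pet_image(array(1, g2$shape), g2)),
               "shell")
})

test_that("AT converges to the exact mask on a sharp sphere and handles degenerates", {
  roi <- sharp_sphere_roi(22)
  res <- segment_lesion(roi$image, "AT")
  expect_true(res$converged)
  expect_identical(res$mask$voxels, roi$truth$voxels)
  # constant image: empty mask, flagged unconverged
  g <- grid_spec(c(8, 8, 8), c(2.73, 2.73, 3.27))
  flat <- segment_lesion(pet_image(array(2, g$shape), g), "AT")
  expect_false(any(flat$mask$voxels))
  expect_false(flat$converged)
})

test_that("RG recovers the sharp sphere exactly and respects connectivity", {
  roi <- sharp_sphere_roi(22)
  res <- segment_lesion(roi$image, "RG")
  expect_identical(res$mask$voxels, roi$truth$voxels)
  # two disconnected hot blobs: only the seeded one is returned
  g <- grid_spec(c(14, 14, 9), c(2.73, 2.73, 3.27))
  v <- array(1, g$shape)
  v[3:5, 3:5, 4:6] <- 6        # larger/hotter blob (the seed)
  v[10:11, 10:11, 4:5] <- 5.5  # disconnected second blob
  res2 <- segment_lesion(pet_image(v, g), "RG")
  expect_true(all(res2$mask$voxels[3:5, 3:5, 4:6]))
  expect_false(any(res2$mask$voxels[10:11, 10:11, 4:5]))
})

test_that("GCM2 separates two-valued images at the midpoint, exactly", {
  roi <- sharp_sphere_roi(17)
  res <- segment_lesion(roi$image, "GCM2")
  expect_identical(res$mask$voxels, roi$truth$voxels)
  expect_lt(abs(min(res$diagnostics$cluster_means) - 1), 1e-6)
  expect_lt(abs(max(res$diagnostics$cluster_means) - 4), 1e-6)
})

test_that("GCM3 labels a three-valued image as background plus two tumour levels", {
  g <- grid_spec(c(12, 12, 9), c(2.73, 2.73, 3.27))
  v <- array(1, g$shape); v[5:8, 5:8, 4:6] <- 4; v[6:7, 6:7, 5] <- 7
  res <- segment_lesion(pet_image(v, g), "GCM3")
  expect_identical(res$mask$voxels, v > 1)
  expect_error(segment_lesion(pet_image(array(1, g$shape), g), "GCM2"),
               "constant")
})

test_that("GCM background cluster always has the lowest mean", {
  entry <- list(id = "S4", battery = "sphere",
                spec = lesion_spec("sphere", 22, "two_level", tbr = 4))
  tpl <- ssphantom:::build_lesion_template(entry)
  pg <- default_pet_grid(tpl$grid)
  noiseless <- simulate_pet(tpl, scanner_config(pg, noiseless = TRUE))
  truth <- extract_ground_truth(tpl, pg)
  roi <- crop_roi(apply_counting_noise(noiseless, 500, 3), truth)
  for (k in c(2, 5, 8)) {
    res <- segment_lesion(roi$image, paste0("GCM", k))
    expect_equal(res$diagnostics$background_cluster,
                 which.min(res$diagnostics$cluster_means))
  }
})

test_that("GCM agrees with an independent fuzzy C-means on well-separated data", {
  skip_if_not_installed("e1071")
  g <- grid_spec(c(10, 10, 7), c(2.73, 2.73, 3.27))
  v <- withr::with_seed(11, {
    a <- array(stats::rnorm(prod(g$shape), 1, 0.05), g$shape)
    a[4:7, 4:7, 3:5] <- stats::rnorm(48, 4, 0.1)
    pmax(a, 0)
  })
  res <- segment_lesion(pet_image(v, g), "GCM2")
  cm <- e1071::cmeans(matrix(as.numeric(v), ncol = 1), centers = 2)
  hi <- which.max(cm$centers)
  expect_identical(as.vector(res$mask$voxels), cm$cluster == hi)
})

test_that("WT recovers the sharp sphere exactly and returns empty on flat ROIs", {
  for (d in c(10, 28)) {
    roi <- sharp_sphere_roi(d)
    res <- segment_lesion(roi$image, "WT")
    expect_identical(res$mask$voxels, roi$truth$voxels)
  }
  g <- grid_spec(c(8, 8, 6), c(2.73, 2.73, 3.27))
  flat <- segment_lesion(pet_image(array(1, g$shape), g), "WT")
  expect_false(any(flat$mask$voxels))
})

test_that("all methods keep the ROI grid and are deterministic", {
  nc <- necrotic_case()
  roi <- crop_roi(apply_counting_noise(nc$noiseless, 500, 5), nc$truth)
  for (m in c("AT", "RG", "GCM4", "WT")) {
    r1 <- segment_lesion(roi$image, m, seed = 5)
    r2 <- segment_lesion(roi$image, m, seed = 5)
    expect_identical(r1$mask$voxels, r2$mask$voxels, info = m)
    expect_identical(r1$mask$grid$shape, roi$image$grid$shape, info = m)
    expect_true(!is.null(r1$diagnostics), info = m)
  }
})

test_that("necrotic cores split the methods: RG fills them, AT and WT do not", {
  nc <- necrotic_case()
  roi <- crop_roi(apply_counting_noise(nc$noiseless, 500, 1), nc$truth)
  core_roi <- crop_like(nc$core, roi)
  n_core <- sum(core_roi$voxels)
  frac <- function(m) {
    res <- segment_lesion(roi$image, m)
    sum(res$mask$voxels & core_roi$voxels) / n_core
  }
  expect_gt(frac("RG"), 0.9)
  expect_lt(frac("AT"), 0.1)
  expect_lt(frac("WT"), 0.1)
})
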