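mk <- function(idx, grid) {
  v <- array(FALSE, grid$shape)
  v[idx] <- TRUE
  binary_mask(v, grid)
}
g8 <- grid_spec(c(8, 8, 8), c(2.73, 2.73, 3.27))

test_that("overlap metrics reproduce their analytic values", {
  A <- mk(1:6, g8); B <- mk(4:7, g8)
  expect_equal(dice(A, B), 2 * 3 / (6 + 4))          # 0.6
  expect_equal(sensitivity(A, B), 0.5)
  expect_equal(ppv(A, B), 0.75)
  expect_equal(dice(A, A), 1)
  expect_equal(dice(A, mk(100:110, g8)), 0)
  expect_error(dice(mk(integer(0), g8), mk(integer(0), g8)), "empty")
  expect_error(sensitivity(mk(integer(0), g8), B), "reference")
  expect_error(ppv(A, mk(integer(0), g8)), "empty")
})

test_that("DSC is the harmonic mean of sensitivity and PPV", {
  withr::with_seed(99, {
    for (i in 1:200) {
      p <- random_mask_pair(g8)
      if (!any(p$A$voxels & p$B$voxels)) next
      d <- dice(p$A, p$B)
      s <- sensitivity(p$A, p$B)
      v <- ppv(p$A, p$B)
      expect_equal(d, 2 / (1 / s + 1 / v), tolerance = 1e-12)
      expect_equal(dice(p$B, p$A), d)
      expect_equal(ppv(p$B, p$A), s)     # symmetry: S(A,B) = PPV(B,A)
      expect_true(all(c(d, s, v) >= 0 & c(d, s, v) <= 1))
    }
  })
})

test_that("the error-bar model and overlap indicator follow their rules", {
  expect_equal(dsc_error_bar(1), 0)
  expect_equal(dsc_error_bar(0), 0.04)
  expect_equal(dsc_error_bar(0.8), 0.008)
  expect_false(good_overlap(0.7))     # strictly above
  expect_true(good_overlap(0.71))
  expect_false(good_overlap(0))
})

test_that("ROI cropping dilates the truth bounding box by ceil(margin/pitch)", {
  g <- grid_spec(c(30, 30, 20), c(2.73, 2.73, 3.27))
  img <- pet_image(array(1, g$shape), g)
  a <- array(FALSE, g$shape); a[14:16, 14:16, 9:11] <- TRUE
  truth <- binary_mask(a, g)
  roi <- crop_roi(img, truth, margin_mm = 10)
  # ceil(10 / 2.73) = 4 in-plane, ceil(10 / 3.27) = 4 axial
  expect_equal(roi$image$grid$shape, c(3 + 8, 3 + 8, 3 + 8))
  expect_false(roi$clipped)
  roi0 <- crop_roi(img, truth, margin_mm = 0)
  expect_equal(roi0$image$grid$shape, c(3, 3, 3))
  # corner truth: clipped flag set, no padding invented
  corner <- binary_mask({a <- array(FALSE, g$shape); a[1:2, 1:2, 1:2] <- TRUE; a}, g)
  roic <- crop_roi(img, corner, margin_mm = 10)
  expect_true(roic$clipped)
  expect_equal(roic$offset, c(1, 1, 1))
  expect_error(crop_roi(img, mk(integer(0), g), 10), "empty")
})

test_that("evaluate_grid yields one record per method x lesion with optimal k", {
  A <- mk(1:20, g8)
  perfect <- mk(1:20, g8)
  half <- mk(11:30, g8)
  res <- list(les1 = list(AT = perfect, GCM2 = half, GCM3 = perfect,
                          GCM4 = half))
  out <- evaluate_grid(res, list(les1 = A))
  expect_equal(nrow(out), 4)
  expect_equal(out$dsc[out$method == "AT"], 1)
  expect_equal(out$sensitivity[out$method == "AT"], 1)
  expect_equal(attr(out, "optimal_clusters")[["les1"]], 3L)
  expect_error(evaluate_grid(res, list(other = A)), "missing ground truth")
  # empty segmentation becomes a flagged zero record, not an error
  res2 <- list(les1 = list(AT = mk(integer(0), g8)))
  out2 <- evaluate_grid(res2, list(les1 = A))
  expect_true(out2$failed)
  expect_equal(out2$dsc, 0)
})
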