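fine_grid <- function(extent_mm = c(70, 70, 70)) {
  shape <- ceiling(extent_mm / c(1, 1, 2))
  grid_spec(shape, c(1, 1, 2))
}

grid_centre <- function(g) g$origin + (g$shape - 1) * g$spacing / 2

test_that("background templates honour structure levels", {
  g <- fine_grid(c(40, 40, 40))
  bg0 <- make_background(g)
  expect_true(all(bg0$values == 1))
  expect_false(any(bg0$lesion_mask$voxels))

  st <- list(centre = grid_centre(g), semi_axes = c(8, 6, 6), level = 0.5)
  bg1 <- make_background(g, list(st))
  inside <- ssphantom:::rasterise_ellipsoid(g, st$centre, st$semi_axes,
                                            volume_match = FALSE)
  expect_equal(mean(bg1$values[inside]), 0.5)
  expect_equal(mean(bg1$values[!inside]), 1.0)

  st2 <- list(centre = grid_centre(g) + c(12, 0, 0),
              semi_axes = c(4, 4, 4), level = 2)
  bg2 <- make_background(g, list(st, st2))
  expect_equal(sort(unique(as.vector(bg2$values))), c(0.5, 1, 2))

  overlapping <- list(st, list(centre = st$centre, semi_axes = c(4, 4, 4),
                               level = 2))
  expect_warning(make_background(g, overlapping), "overlap")
})

test_that("homogeneous lesions print tbr x background and match the analytic volume", {
  g <- fine_grid(c(80, 80, 80))
  bg <- make_background(g)
  tpl <- make_lesion_template(
    bg, lesion_spec("sphere", 38, "homogeneous", tbr = 4,
                    centre = grid_centre(g)))
  expect_true(all(tpl$values[tpl$lesion_mask$voxels] == 4))
  vol <- mask_volume_ml(tpl$lesion_mask)
  expect_lt(abs(vol - 28.73) / 28.73, 0.02)
})

test_that("rasterised sphere volumes match 4/3 pi r^3 within 2% for S1-S6", {
  for (d in sphere_battery_diameters()) {
    g <- fine_grid(rep(d + 44, 3))
    tpl <- make_lesion_template(
      make_background(g),
      lesion_spec("sphere", d, "homogeneous", tbr = 4,
                  centre = grid_centre(g)))
    analytic <- 4 / 3 * pi * (d / 2)^3 / 1000
    expect_lt(abs(mask_volume_ml(tpl$lesion_mask) - analytic) / analytic,
              0.02)
  }
})

test_that("two-level uptake obeys the equal-contrast rule H - L = L - B", {
  g <- fine_grid(c(60, 60, 60))
  tpl <- make_lesion_template(
    make_background(g),
    lesion_spec("sphere", 10, "two_level", tbr = 4,
                centre = grid_centre(g)))
  vals <- sort(unique(as.vector(tpl$values)))
  expect_equal(vals, c(1, 4, 7))     # B = 1, L = 4, H = 2L - B = 7
  expect_identical((vals[3] - vals[2]) - (vals[2] - vals[1]), 0)
  # the inner high region is strictly inside the lesion
  high <- tpl$values == 7
  expect_true(all(tpl$lesion_mask$voxels[high]))
  expect_lt(sum(high), sum(tpl$lesion_mask$voxels))
})

test_that("necrotic lesions print a zero-uptake core excluded from the ground truth", {
  g <- fine_grid(c(80, 80, 80))
  tpl <- make_lesion_template(
    make_background(g),
    lesion_spec("spheroid", 11, "necrotic", tbr = 4,
                centre = grid_centre(g)))
  core <- tpl$core_mask$voxels
  expect_true(any(core))
  expect_true(all(tpl$values[core] == 0))
  # delivered ground truth excludes the core; the outer shape contains both
  expect_false(any(tpl$lesion_mask$voxels & core))
  expect_true(all(core | tpl$lesion_mask$voxels == tpl$outer_mask$voxels))
  expect_true(all((tpl$lesion_mask$voxels | core) == tpl$outer_mask$voxels))
  # core is ~40% of the outer volume
  frac <- sum(core) / sum(tpl$outer_mask$voxels)
  expect_lt(abs(frac - 0.4), 0.05)
})

test_that("gaussian patterns peak centrally and stay above background", {
  g <- fine_grid(c(80, 80, 80))
  tpl <- make_lesion_template(
    make_background(g),
    lesion_spec("spheroid", 11, "gaussian", tbr = 4,
                centre = grid_centre(g)))
  ctr_idx <- world_to_index(g, grid_centre(g))
  centre_val <- tpl$values[ctr_idx[1], ctr_idx[2], ctr_idx[3]]
  expect_gt(centre_val, 2)                      # raised uptake at the centre
  expect_lt(centre_val, 4 + 1e-9)               # bounded by the plateau level
  expect_true(all(tpl$values >= 1 - 1e-9))
  # smoothed: strictly fewer unique values than a homogeneous insert
  expect_gt(length(unique(as.vector(tpl$values))), 10)
})

test_that("lesions must clear the grid edge by 10 mm", {
  g <- fine_grid(c(40, 40, 40))
  expect_error(
    make_lesion_template(make_background(g),
                         lesion_spec("sphere", 38, "homogeneous", tbr = 4,
                                     centre = grid_centre(g))),
    "clearance")
})
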