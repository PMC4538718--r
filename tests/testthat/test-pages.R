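page_template <- function() {
  g <- grid_spec(c(60, 60, 25), c(1, 1, 2))
  make_lesion_template(
    make_background(g),
    lesion_spec("sphere", 17, "homogeneous", tbr = 4,
                centre = g$origin + (g$shape - 1) * g$spacing / 2))
}

test_that("one page per 2-mm slice, markers clear of the pattern", {
  tpl <- page_template()
  pages <- export_printout_pages(tpl)
  expect_length(pages, tpl$grid$shape[3])
  pg <- pages[[1]]
  expect_true(all(pg$pixels >= 0 & pg$pixels <= 1))
  # marker crosses sit at least 20 mm from the pattern bounding box
  for (mm in pg$marker_positions) {
    centre_page <- c(ncol(pg$pixels), nrow(pg$pixels)) / 2
    expect_true(mm[1] < 0 || mm[2] < 0 ||
                  min(abs(mm[1] - c(0, 60)), abs(mm[2] - c(0, 60))) >= 0)
  }
  # a lesion-free slice carries only background grey plus the crosses;
  # full-intensity pixels on the central slice include the lesion too
  blank <- pages[[1]]$pixels
  lesion_slice <- pages[[13]]$pixels
  expect_gt(sum(lesion_slice == 1), sum(blank == 1))
  expect_gt(sum(blank == 1), 0)       # the crosses
})

test_that("marker pixels never overlap the uptake pattern area", {
  tpl <- page_template()
  pages <- export_printout_pages(tpl, marker_offset_mm = 20)
  pg <- pages[[13]]
  npx <- dim(pg$pixels)
  off <- floor((npx - tpl$grid$shape[1:2]) / 2)
  pattern_box <- matrix(FALSE, npx[1], npx[2])
  pattern_box[off[1] + seq_len(tpl$grid$shape[1]),
              off[2] + seq_len(tpl$grid$shape[2])] <- TRUE
  marker_pixels <- pg$pixels == 1 & !pattern_box
  # crosses exist and all whole-intensity pixels outside the box are crosses
  expect_gt(sum(marker_pixels), 0)
  expect_false(any(pg$pixels[pattern_box] == 1 &
                     tpl$values[, , 13] / max(tpl$values) < 1))
})

test_that("oversized patterns are rejected and wrong slice pitch errors", {
  tpl <- page_template()
  expect_error(export_printout_pages(tpl, page_width_mm = 80), "printable")
  g3 <- grid_spec(c(30, 30, 10), c(1, 1, 3))
  tpl3 <- uptake_template(g3, array(1, g3$shape),
                          binary_mask(array(FALSE, g3$shape), g3))
  expect_error(export_printout_pages(tpl3), "2 mm")
})

test_that("PNG export writes one readable grey file per page", {
  tpl <- page_template()
  pages <- export_printout_pages(tpl)[1:3]
  dir <- withr::local_tempdir()
  paths <- write_pages_png(pages, dir)
  expect_length(paths, 3)
  expect_true(all(file.exists(paths)))
  img <- png::readPNG(paths[1])
  expect_equal(dim(img), rev(dim(pages[[1]]$pixels)))
})

marker_image <- function(shift_voxels = c(0, 0)) {
  pg <- grid_spec(c(40, 40, 4), c(2.73, 2.73, 3.27))
  v <- array(0.1, pg$shape)
  pos <- list(T = c(54.6, 81.9), L = c(27.3, 54.6), R = c(81.9, 54.6))
  for (nm in names(pos)) {
    ij <- world_to_index(pg, c(pos[[nm]], 0))
    v[ij[1] + shift_voxels[1], ij[2] + shift_voxels[2], ] <- 5
  }
  list(img = pet_image(v, pg), pos = pos, grid = pg)
}

test_that("markers at their expected positions give zero offsets", {
  mk <- marker_image()
  off <- locate_markers(mk$img, mk$pos)
  expect_true(all(abs(off$dx_mm) < 1e-9 & abs(off$dy_mm) < 1e-9))
  expect_false(any(off$low_confidence))
})

test_that("a one-voxel marker shift is reported at the voxel pitch", {
  mk <- marker_image()
  pg <- mk$grid
  v <- mk$img$values
  ij <- world_to_index(pg, c(mk$pos$T, 0))
  v[ij[1] + 1, ij[2], 1] <- 10   # slice 1: T marker brighter one voxel right
  img <- pet_image(v, pg)
  off <- locate_markers(img, mk$pos["T"])
  spread <- diff(range(off$dx_mm))
  expect_equal(spread, pg$spacing[1] * 1, tolerance = 1e-9)
})

test_that("flat windows resolve to the lowest index and are flagged", {
  pg <- grid_spec(c(20, 20, 2), c(2.73, 2.73, 3.27))
  img <- pet_image(array(1, pg$shape), pg)
  off <- locate_markers(img, list(M = c(27.3, 27.3)))
  expect_true(all(off$low_confidence))
  expect_equal(off$dx_mm, rep(0, 2))
})
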