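#' Export print-ready page images for each template slice
#'
#' One grey-level page per 2-mm axial slice: template values are mapped
#' linearly to \[0, 1\] grey (relative to the template maximum; printer
#' calibration is applied separately, see [grey_for_target_activity()]),
#' and cross-shaped alignment markers are drawn at the top (T), left (L) and
#' right (R) of the pattern at the requested offset.
#'
#' @param template an `uptake_template` with 2-mm axial spacing.
#' @param page_width_mm,page_height_mm printable page size (default
#'   168 x 197 mm, the sheet cut to fit the phantom).
#' @param marker_offset_mm distance between the markers and the pattern
#'   bounding box (default 20 mm).
#' @param marker_arm_mm half-length of each cross arm (default 4 mm).
#' @return A list of `page_image` objects, one per slice, each with elements
#'   `page_index`, `pixels` (2-D grey array in \[0,1\], row = x, col = y) and
#'   `marker_positions` (named list of T/L/R mm page coordinates).
#' @export
export_printout_pages <- function(template, page_width_mm = 168,
                                  page_height_mm = 197,
                                  marker_offset_mm = 20,
                                  marker_arm_mm = 4) {
  grid <- template$grid
  if (abs(grid$spacing[3] - 2) > 1e-9)
    stop("export_printout_pages: template axial spacing must be 2 mm ",
         "(one page per slice)")
  sp <- grid$spacing[1:2]
  pattern_extent <- grid$shape[1:2] * sp
  need <- pattern_extent + 2 * (marker_offset_mm + 2 * marker_arm_mm)
  if (need[1] > page_width_mm || need[2] > page_height_mm)
    stop("export_printout_pages: pattern plus markers exceeds the ",
         "printable area")
  npx <- c(ceiling(page_width_mm / sp[1]), ceiling(page_height_mm / sp[2]))
  # centre the pattern on the page
  off <- floor((npx - grid$shape[1:2]) / 2)
  vmax <- max(template$values)
  if (vmax <= 0) vmax <- 1
  bbox_lo_mm <- off * sp
  bbox_hi_mm <- (off + grid$shape[1:2]) * sp
  marker_mm <- list(
    T = c((bbox_lo_mm[1] + bbox_hi_mm[1]) / 2, bbox_hi_mm[2] + marker_offset_mm),
    L = c(bbox_lo_mm[1] - marker_offset_mm, (bbox_lo_mm[2] + bbox_hi_mm[2]) / 2),
    R = c(bbox_hi_mm[1] + marker_offset_mm, (bbox_lo_mm[2] + bbox_hi_mm[2]) / 2))
  arm_px <- ceiling(marker_arm_mm / sp)
  draw_cross <- function(pix, mm) {
    ij <- pmax(pmin(round(mm / sp) + 1L, npx), 1L)
    xs <- max(1L, ij[1] - arm_px[1]):min(npx[1], ij[1] + arm_px[1])
    ys <- max(1L, ij[2] - arm_px[2]):min(npx[2], ij[2] + arm_px[2])
    pix[xs, ij[2]] <- 1
    pix[ij[1], ys] <- 1
    pix
  }
  lapply(seq_len(grid$shape[3]), function(k) {
    pix <- matrix(0, npx[1], npx[2])
    pix[off[1] + seq_len(grid$shape[1]), off[2] + seq_len(grid$shape[2])] <-
      template$values[, , k] / vmax
    for (m in marker_mm) pix <- draw_cross(pix, m)
    structure(list(page_index = k, pixels = pix,
                   marker_positions = marker_mm),
              class = "page_image")
  })
}

#' Write page images as 8-bit grey PNG files
#'
#' @param pages list of `page_image` from [export_printout_pages()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return Invisibly, the written file paths.
#' @export
write_pages_png <- function(pages, dir, prefix = "page") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(pages, function(pg) {
    path <- file.path(dir, sprintf("%s_%03d.png", prefix, pg$page_index))
    # png images are row-major from the top; transpose and flip y
    img <- t(pg$pixels[, rev(seq_len(ncol(pg$pixels)))])
    png::writePNG(pmin(pmax(img, 0), 1), path)
    path
  }, character(1))
  invisible(paths)
}

#' Locate alignment markers on a PET image
#'
#' For every axial slice and every expected marker position, finds the
#' highest-intensity voxel within a `window` x `window` in-plane square
#' centred on the expected position, and reports the mm offset of that voxel
#' from the marker's mean located position across slices. Flat windows are
#' resolved to the lowest linear index and flagged low-confidence.
#'
#' @param image a `pet_image`.
#' @param expected_positions named list of in-plane mm coordinates (length-2
#'   numeric vectors), e.g. `list(T = ..., L = ..., R = ...)`.
#' @param window odd window edge length in voxels (default 5).
#' @param slices axial slice indices to inspect (default all).
#' @return A data.frame with columns `marker`, `slice`, `dx_mm`, `dy_mm`,
#'   `low_confidence`.
#' @export
locate_markers <- function(image, expected_positions, window = 5L,
                           slices = NULL) {
  grid <- image$grid
  if (window %% 2L != 1L) stop("locate_markers: window must be odd")
  h <- (window - 1L) %/% 2L
  if (is.null(slices)) slices <- seq_len(grid$shape[3])
  if (is.null(names(expected_positions)))
    names(expected_positions) <- paste0("M", seq_along(expected_positions))
  rows <- list()
  for (mk in names(expected_positions)) {
    mm <- expected_positions[[mk]]
    ij <- c(round((mm[1] - grid$origin[1]) / grid$spacing[1]) + 1L,
            round((mm[2] - grid$origin[2]) / grid$spacing[2]) + 1L)
    if (any(ij < 1L) || ij[1] > grid$shape[1] || ij[2] > grid$shape[2])
      stop("locate_markers: expected position outside the image: ", mk)
    xs <- (ij[1] - h):(ij[1] + h)
    ys <- (ij[2] - h):(ij[2] + h)
    if (any(xs < 1L) || any(xs > grid$shape[1]) ||
        any(ys < 1L) || any(ys > grid$shape[2])) {
      warning("locate_markers: window clipped at image boundary for ", mk)
      xs <- xs[xs >= 1L & xs <= grid$shape[1]]
      ys <- ys[ys >= 1L & ys <= grid$shape[2]]
    }
    found <- t(vapply(slices, function(k) {
      w <- image$values[xs, ys, k]
      flat <- max(w) - min(w) <= 0
      best <- which.max(w)              # lowest linear index on ties
      sub <- arrayInd(best, dim(w))
      c(x = grid$origin[1] + (xs[sub[1]] - 1) * grid$spacing[1],
        y = grid$origin[2] + (ys[sub[2]] - 1) * grid$spacing[2],
        flat = as.numeric(flat))
    }, numeric(3)))
    mean_pos <- colMeans(found[, 1:2, drop = FALSE])
    rows[[mk]] <- data.frame(marker = mk, slice = slices,
                             dx_mm = found[, 1] - mean_pos[1],
                             dy_mm = found[, 2] - mean_pos[2],
                             low_confidence = found[, 3] > 0)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
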