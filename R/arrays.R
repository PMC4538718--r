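# Low-level 3-D array primitives: shifts, separable convolution, connected
# components, hole filling. No installed package offers 3-D 26-connected
# labelling or cavity filling, so these are implemented here and shared by the
# simulator and the segmentation methods.

# Shift a 3-D array by n voxels along one axis, zero-filling the vacated part.
shift_array <- function(a, n, axis) {
  if (n == 0L) return(a)
  d <- dim(a)
  out <- array(0, d)
  m <- d[axis]
  if (abs(n) >= m) return(out)
  src <- if (n > 0) 1:(m - n) else (1 - n):m
  dst <- if (n > 0) (1 + n):m else 1:(m + n)
  ix <- list(1:d[1], 1:d[2], 1:d[3])
  ixs <- ix; ixs[[axis]] <- src
  ixd <- ix; ixd[[axis]] <- dst
  out[ixd[[1]], ixd[[2]], ixd[[3]]] <- a[ixs[[1]], ixs[[2]], ixs[[3]]]
  out
}

# Normalised 1-D Gaussian kernel sampled at the voxel pitch; radius 4 sigma so
# a compactly supported source loses < 1e-4 of its mass to truncation.
gaussian_kernel_1d <- function(sigma_mm, pitch_mm) {
  if (sigma_mm <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_mm / pitch_mm))
  k <- stats::dnorm((-r:r) * pitch_mm, sd = sigma_mm)
  k / sum(k)
}

# Separable Gaussian blur of a 3-D array, zero padding implied at the edges.
# fwhm_mm may be scalar (isotropic) or length 3.
gaussian_blur_3d <- function(a, fwhm_mm, spacing) {
  fwhm_mm <- rep_len(fwhm_mm, 3L)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  for (axis in 1:3) {
    if (sigma[axis] <= 0) next
    k <- gaussian_kernel_1d(sigma[axis], spacing[axis])
    r <- (length(k) - 1L) %/% 2L
    acc <- array(0, dim(a))
    for (j in -r:r) acc <- acc + k[j + r + 1L] * shift_array(a, j, axis)
    a <- acc
  }
  a
}

# Neighbour index offsets for a flattened 3-D array.
neighbour_offsets <- function(d, connectivity = 26L) {
  sx <- 1L; sy <- d[1]; sz <- d[1] * d[2]
  if (connectivity == 6L) {
    steps <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else {
    steps <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    steps <- steps[rowSums(abs(steps)) > 0, , drop = FALSE]
  }
  list(steps = steps, strides = c(sx, sy, sz))
}

# Label connected components of a logical 3-D array (26- or 6-connectivity).
# Returns an integer array, 0 = background, components numbered from 1 in
# order of their lowest linear index. BFS over vectorised frontiers.
label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  nb <- neighbour_offsets(d, connectivity)
  lab <- array(0L, d)
  remaining <- which(mask)
  comp <- 0L
  # voxel coordinates for boundary checks
  coord <- function(idx) {
    i0 <- idx - 1L
    cbind(i0 %% d[1], (i0 %/% d[1]) %% d[2], i0 %/% (d[1] * d[2]))
  }
  while (length(remaining) > 0) {
    seedpos <- remaining[1L]
    comp <- comp + 1L
    lab[seedpos] <- comp
    frontier <- seedpos
    while (length(frontier) > 0) {
      fc <- coord(frontier)
      cand <- integer(0)
      for (s in seq_len(nrow(nb$steps))) {
        st <- nb$steps[s, ]
        ok <- fc[, 1] + st[1] >= 0 & fc[, 1] + st[1] < d[1] &
              fc[, 2] + st[2] >= 0 & fc[, 2] + st[2] < d[2] &
              fc[, 3] + st[3] >= 0 & fc[, 3] + st[3] < d[3]
        if (!any(ok)) next
        cand <- c(cand, frontier[ok] + sum(st * nb$strides))
      }
      cand <- unique(cand)
      cand <- cand[mask[cand] & lab[cand] == 0L]
      lab[cand] <- comp
      frontier <- cand
    }
    remaining <- remaining[lab[remaining] == 0L]
  }
  lab
}

# Largest connected component of a logical array; empty input returns empty.
largest_component <- function(mask, connectivity = 26L) {
  if (!any(mask)) return(mask)
  lab <- label_components(mask, connectivity)
  tab <- tabulate(lab[lab > 0L])
  lab == which.max(tab)
}

# Fill enclosed cavities of a 3-D mask: background is flooded 6-connected from
# the array border; anything not reached and not foreground is a cavity.
fill_holes_3d <- function(mask) {
  d <- dim(mask)
  outside <- array(FALSE, d)
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  frontier <- which(border & !mask)
  outside[frontier] <- TRUE
  nb <- neighbour_offsets(d, 6L)
  coord <- function(idx) {
    i0 <- idx - 1L
    cbind(i0 %% d[1], (i0 %/% d[1]) %% d[2], i0 %/% (d[1] * d[2]))
  }
  while (length(frontier) > 0) {
    fc <- coord(frontier)
    cand <- integer(0)
    for (s in seq_len(nrow(nb$steps))) {
      st <- nb$steps[s, ]
      ok <- fc[, 1] + st[1] >= 0 & fc[, 1] + st[1] < d[1] &
            fc[, 2] + st[2] >= 0 & fc[, 2] + st[2] < d[2] &
            fc[, 3] + st[3] >= 0 & fc[, 3] + st[3] < d[3]
      if (!any(ok)) next
      cand <- c(cand, frontier[ok] + sum(st * nb$strides))
    }
    cand <- unique(cand)
    cand <- cand[!mask[cand] & !outside[cand]]
    outside[cand] <- TRUE
    frontier <- cand
  }
  mask | !outside
}

# Mean filter over the 3x3x3 neighbourhood with zero padding (fixed
# denominator 27). Truncated means would inflate edge voxels, pulling
# seed-finding maxima into corners; zero padding biases mildly against the
# edges instead, which is the safe direction for interior lesions.
box_mean_3x3x3 <- function(a) {
  d <- dim(a)
  acc <- array(0, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    acc <- acc + shift_array(shift_array(shift_array(a, dx, 1), dy, 2), dz, 3)
  }
  acc / 27
}

# Fill enclosed 2-D holes slice by slice (axial): flood the complement
# 4-connected from the slice border. Fills annular cross-sections even when
# a thin polar cap leaves the 3-D shell open, matching the slice-wise
# fill idiom common in PET segmentation pipelines.
fill_holes_slicewise <- function(mask) {
  d <- dim(mask)
  for (k in seq_len(d[3])) {
    sl <- mask[, , k]
    if (!any(sl)) next
    outside <- matrix(FALSE, d[1], d[2])
    border <- (row(sl) %in% c(1L, d[1])) | (col(sl) %in% c(1L, d[2]))
    frontier <- which(border & !sl)
    outside[frontier] <- TRUE
    while (length(frontier)) {
      x <- (frontier - 1L) %% d[1]
      y <- (frontier - 1L) %/% d[1]
      cand <- unique(c(frontier[x > 0L] - 1L,
                       frontier[x < d[1] - 1L] + 1L,
                       frontier[y > 0L] - d[1],
                       frontier[y < d[2] - 1L] + d[1]))
      cand <- cand[!sl[cand] & !outside[cand]]
      outside[cand] <- TRUE
      frontier <- cand
    }
    mask[, , k] <- sl | !outside
  }
  mask
}
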