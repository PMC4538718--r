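# Shared fixtures and independent oracles, built in code at test time.

# A sharp two-valued sphere phantom directly on the PET grid (no blur, no
# noise), cropped to the 10-mm ROI; the configuration of the noiseless
# oracle-equivalence checks.
sharp_sphere_roi <- function(diameter_mm, tbr = 4,
                             spacing = c(2.73, 2.73, 3.27)) {
  n <- ceiling((diameter_mm + 44) / spacing)
  pg <- grid_spec(n, spacing)
  bg <- make_background(pg)
  ctr <- pg$origin + (pg$shape - 1) * pg$spacing / 2
  tpl <- make_lesion_template(
    bg, lesion_spec("sphere", diameter_mm, "homogeneous", tbr = tbr,
                    centre = ctr))
  img <- simulate_pet(tpl, scanner_config(pg, psf_fwhm_mm = 0,
                                          noiseless = TRUE))
  crop_roi(img, extract_ground_truth(tpl, pg))
}

# Independent oracle: the connected component of {v >= thr} containing the
# global maximum, found by a deliberately simple stack-based flood fill
# (no shared code with the package internals).
oracle_threshold_component <- function(v, thr) {
  d <- dim(v)
  inside <- v >= thr
  comp <- array(FALSE, d)
  start <- arrayInd(which.max(v), d)
  stack <- list(as.integer(start))
  while (length(stack)) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (p[1] < 1 || p[1] > d[1] || p[2] < 1 || p[2] > d[2] ||
        p[3] < 1 || p[3] > d[3]) next
    if (!inside[p[1], p[2], p[3]] || comp[p[1], p[2], p[3]]) next
    comp[p[1], p[2], p[3]] <- TRUE
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      stack[[length(stack) + 1L]] <- c(p[1] + dx, p[2] + dy, p[3] + dz)
    }
  }
  comp
}

# Random masks sharing a grid, for the metric identity properties.
random_mask_pair <- function(grid, p_a = 0.3, p_b = 0.3) {
  n <- prod(grid$shape)
  A <- binary_mask(array(stats::runif(n) < p_a, grid$shape), grid)
  B <- binary_mask(array(stats::runif(n) < p_b, grid$shape), grid)
  list(A = A, B = B)
}

# Noiseless simulated necrotic spheroid shared across tests (built once).
necrotic_case <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      entry <- list(id = "spheroid_necrotic", battery = "lesion",
                    spec = lesion_spec("spheroid", 11, "necrotic", tbr = 4))
      cfg <- experiment_config(list(entry))
      tpl <- ssphantom:::build_lesion_template(entry)
      pg <- default_pet_grid(tpl$grid, cfg$pet_spacing)
      noiseless <- simulate_pet(tpl, scanner_config(pg, noiseless = TRUE))
      cache <<- list(template = tpl, pet_grid = pg, noiseless = noiseless,
                     truth = extract_ground_truth(tpl, pg),
                     core = extract_ground_truth(tpl, pg, "core"))
    }
    cache
  }
})

# Crop a companion mask with the offsets recorded by crop_roi().
crop_like <- function(mask, roi) {
  off <- roi$offset
  sh <- roi$image$grid$shape
  binary_mask(mask$voxels[off[1]:(off[1] + sh[1] - 1),
                          off[2]:(off[2] + sh[2] - 1),
                          off[3]:(off[3] + sh[3] - 1), drop = FALSE],
              roi$image$grid)
}
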