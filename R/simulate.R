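#' Scanner configuration for the simplified PET simulator
#'
#' The simulator stands in for acquisition plus reconstruction with three
#' steps: volume-conserving resampling of the fine template onto the PET
#' grid, isotropic Gaussian blurring (a single point-spread kernel folding
#' scanner resolution and the post-reconstruction filter together), and
#' Poisson counting noise on the blurred means.
#'
#' @param pet_grid a `grid_spec` for the reconstructed image (clinical
#'   default voxels: 2.73 x 2.73 x 3.27 mm).
#' @param psf_fwhm_mm full width at half maximum of the Gaussian point
#'   spread, mm (default 6.4, the clinical post-filter cut-off).
#' @param noise_scale expected counts per unit relative activity per voxel
#'   (default 500); larger values mean less relative noise.
#' @param noise_seed integer seed for the Poisson draw.
#' @param noiseless if `TRUE`, skip the noise step.
#' @return An object of class `scanner_config`.
#' @export
scanner_config <- function(pet_grid, psf_fwhm_mm = 6.4, noise_scale = 500,
                           noise_seed = 1L, noiseless = FALSE) {
  stopifnot_grid(pet_grid)
  if (psf_fwhm_mm < 0) stop("scanner_config: psf_fwhm_mm must be >= 0")
  if (!noiseless && noise_scale <= 0)
    stop("scanner_config: noise_scale must be > 0 unless noiseless")
  structure(list(pet_grid = pet_grid, psf_fwhm_mm = psf_fwhm_mm,
                 noise_scale = noise_scale,
                 noise_seed = as.integer(noise_seed),
                 noiseless = isTRUE(noiseless)),
            class = "scanner_config")
}

#' PET image container
#'
#' @param values 3-D non-negative array of image intensities.
#' @param grid the `grid_spec` the image lives on.
#' @param provenance free text, e.g. `"simulated"` or `"file"`.
#' @return An object of class `pet_image`.
#' @export
pet_image <- function(values, grid, provenance = "simulated") {
  stopifnot_grid(grid)
  if (!all(dim(values) == grid$shape))
    stop("pet_image: values shape does not match grid")
  if (any(!is.finite(values))) stop("pet_image: values must be finite")
  if (any(values < 0)) stop("pet_image: values must be >= 0")
  structure(list(grid = grid, values = values, provenance = provenance),
            class = "pet_image")
}

#' @export
print.pet_image <- function(x, ...) {
  cat(sprintf("<pet_image> %s voxels (%s), range [%.3g, %.3g]\n",
              paste(x$grid$shape, collapse = " x "), x$provenance,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Default PET grid covering a template
#'
#' Builds a PET-resolution grid whose voxel intervals cover the template's
#' physical extent (the last voxel may overhang).
#'
#' @param template_grid the fine `grid_spec` to cover.
#' @param spacing PET voxel size in mm (default `c(2.73, 2.73, 3.27)`).
#' @export
default_pet_grid <- function(template_grid, spacing = c(2.73, 2.73, 3.27)) {
  extent <- template_grid$shape * template_grid$spacing
  shape <- pmax(ceiling(extent / spacing - 1e-9), 1)
  edge <- template_grid$origin - template_grid$spacing / 2
  grid_spec(shape, spacing, origin = edge + spacing / 2)
}

## ---- volume-conserving resampling ----------------------------------------

# Interval-overlap weight matrix mapping n_in cells to n_out cells along one
# axis. Row i holds the fractional overlap of output cell i with each input
# cell, divided by the output cell width: applying it averages the input
# signal over each output cell, so integral (value x cell width) is conserved
# wherever the input covers the output.
overlap_matrix <- function(in_centres, in_width, out_centres, out_width) {
  n_in <- length(in_centres); n_out <- length(out_centres)
  in_lo <- in_centres - in_width / 2; in_hi <- in_centres + in_width / 2
  out_lo <- out_centres - out_width / 2; out_hi <- out_centres + out_width / 2
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    ov <- pmin(out_hi[i], in_hi) - pmax(out_lo[i], in_lo)
    pos <- ov > 0
    if (any(pos)) W[i, pos] <- ov[pos] / out_width
  }
  W
}

apply_axis_matrix <- function(a, W, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- W %*% matrix(ap, nrow = d[axis])
  out <- array(m, c(nrow(W), d[perm[2]], d[perm[3]]))
  aperm(out, order(perm))
}

#' Volume-conserving resample of a 3-D array between grids
#'
#' Each output voxel takes the average of the input signal over its interval
#' (per-axis interval overlap weights), so total integrated activity is
#' conserved wherever the input grid covers the output grid. Identical grids
#' return the input unchanged.
#'
#' @param values 3-D array on `from` grid.
#' @param from,to `grid_spec`s.
#' @return 3-D array on the `to` grid.
#' @export
resample_volume <- function(values, from, to) {
  if (grids_identical(from, to)) return(values)
  for (axis in 1:3) {
    W <- overlap_matrix(grid_axis_coords(from, axis), from$spacing[axis],
                        grid_axis_coords(to, axis), to$spacing[axis])
    values <- apply_axis_matrix(values, W, axis)
    # collapse the processed axis of `from` onto the target description
    from <- grid_spec(replace(from$shape, axis, to$shape[axis]),
                      replace(from$spacing, axis, to$spacing[axis]),
                      replace(from$origin, axis, to$origin[axis]))
  }
  values
}

#' Apply Poisson counting noise to an image
#'
#' Each voxel is drawn from a Poisson law with mean `noise_scale * value`
#' and divided by `noise_scale`, leaving the expectation unchanged.
#' Deterministic for a fixed seed.
#'
#' @param image a `pet_image`.
#' @param noise_scale expected counts per unit intensity per voxel.
#' @param noise_seed integer seed.
#' @export
apply_counting_noise <- function(image, noise_scale, noise_seed) {
  vals <- withr::with_seed(as.integer(noise_seed), {
    array(stats::rpois(length(image$values),
                       lambda = noise_scale * image$values) / noise_scale,
          dim(image$values))
  })
  pet_image(vals, image$grid, provenance = image$provenance)
}

#' Simulate a PET image from an uptake template
#'
#' Pipeline: (1) volume-conserving resample of the template onto the PET
#' grid, (2) 3-D Gaussian blur at the configured FWHM, (3) unless
#' `noiseless`, Poisson counting noise (see [apply_counting_noise()]).
#'
#' @param template an `uptake_template`.
#' @param cfg a [scanner_config()].
#' @return A `pet_image` with provenance `"simulated"`.
#' @examples
#' g <- grid_spec(c(60, 60, 30), c(1, 1, 2))
#' bg <- make_background(g)
#' spec <- lesion_spec("sphere", 17, "homogeneous",
#'                     centre = c(29.5, 29.5, 29))
#' tpl <- make_lesion_template(bg, spec)
#' img <- simulate_pet(tpl, scanner_config(default_pet_grid(g),
#'                                         noiseless = TRUE))
#' @export
simulate_pet <- function(template, cfg) {
  if (!inherits(template, "uptake_template"))
    stop("simulate_pet: template must be an uptake_template")
  if (!inherits(cfg, "scanner_config"))
    stop("simulate_pet: cfg must be a scanner_config")
  if (any(template$values < 0))
    stop("simulate_pet: template values must be >= 0")
  vals <- resample_volume(template$values, template$grid, cfg$pet_grid)
  vals <- gaussian_blur_3d(vals, cfg$psf_fwhm_mm, cfg$pet_grid$spacing)
  vals <- pmax(vals, 0)
  img <- pet_image(vals, cfg$pet_grid, provenance = "simulated")
  if (!cfg$noiseless)
    img <- apply_counting_noise(img, cfg$noise_scale, cfg$noise_seed)
  img
}

#' Resample a ground-truth mask onto the PET grid
#'
#' A PET voxel is true iff its fractional coverage by the fine-grid mask is
#' at least 0.5. With `pet_grid` equal to the template grid the mask is
#' returned unchanged.
#'
#' @param template an `uptake_template` with a non-empty lesion mask.
#' @param pet_grid target `grid_spec`.
#' @param which_mask `"lesion"` (default, the delivered ground truth),
#'   `"core"` or `"outer"`.
#' @return A `binary_mask` on `pet_grid`.
#' @export
extract_ground_truth <- function(template, pet_grid,
                                 which_mask = c("lesion", "core", "outer")) {
  which_mask <- match.arg(which_mask)
  src <- switch(which_mask,
                lesion = template$lesion_mask,
                core = template$core_mask,
                outer = template$outer_mask)
  if (is.null(src) || !any(src$voxels))
    stop("extract_ground_truth: requested mask is empty")
  if (grids_identical(template$grid, pet_grid))
    return(binary_mask(src$voxels, pet_grid))
  cov <- resample_volume(array(as.numeric(src$voxels), dim(src$voxels)),
                         template$grid, pet_grid)
  binary_mask(cov >= 0.5, pet_grid)
}
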