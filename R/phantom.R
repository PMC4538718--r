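#' Lesion specification
#'
#' Declarative description of one model lesion: its shape, size, uptake
#' pattern and tumour-to-background ratio (TBR). Sizes are a diameter in mm
#' for spheres and a target volume in mL for spheroids and irregular shapes.
#'
#' The available uptake patterns mirror the five modelled tumour types:
#' `homogeneous` (uniform uptake at TBR times the local background),
#' `two_level` (low rim L and concentric high centre H with H - L = L - B),
#' `gaussian` (homogeneous excess smoothed with a Gaussian kernel),
#' `necrotic` (homogeneous rim with a zero-uptake central core) and
#' `necrotic_gaussian` (the necrotic pattern Gaussian-smoothed).
#'
#' @param shape_kind one of `"sphere"`, `"spheroid"`, `"irregular"`.
#' @param size diameter in mm (sphere) or target volume in mL (others).
#' @param pattern one of the five pattern names above.
#' @param tbr tumour-to-background ratio (> 1), default 4.
#' @param centre mm world coordinates of the lesion centre.
#' @param shape_seed integer seed for the irregular shape generator.
#' @param inner_fraction for `two_level`: diameter fraction of the central
#'   high-uptake region (default 0.5).
#' @param core_fraction for necrotic patterns: volume fraction of the
#'   zero-uptake core (default 0.4).
#' @param smooth_fwhm_mm Gaussian pattern kernel FWHM in mm; `NULL` (default)
#'   uses half the lesion's volume-equivalent diameter.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(shape_kind = c("sphere", "spheroid", "irregular"),
                        size, pattern = c("homogeneous", "two_level",
                                          "gaussian", "necrotic",
                                          "necrotic_gaussian"),
                        tbr = 4, centre = c(0, 0, 0), shape_seed = 1L,
                        inner_fraction = 0.5, core_fraction = 0.4,
                        smooth_fwhm_mm = NULL) {
  shape_kind <- match.arg(shape_kind)
  pattern <- match.arg(pattern)
  if (!is.numeric(size) || size <= 0) stop("lesion_spec: size must be > 0")
  if (!is.numeric(tbr) || tbr <= 1) stop("lesion_spec: tbr must be > 1")
  if (inner_fraction <= 0 || inner_fraction >= 1)
    stop("lesion_spec: inner_fraction must be in (0,1)")
  if (core_fraction <= 0 || core_fraction >= 1)
    stop("lesion_spec: core_fraction must be in (0,1)")
  structure(list(shape_kind = shape_kind, size = size, pattern = pattern,
                 tbr = tbr, centre = as.numeric(centre),
                 shape_seed = as.integer(shape_seed),
                 inner_fraction = inner_fraction,
                 core_fraction = core_fraction,
                 smooth_fwhm_mm = smooth_fwhm_mm),
            class = "lesion_spec")
}

# Volume-equivalent diameter in mm for any lesion spec.
equivalent_diameter_mm <- function(spec) {
  if (spec$shape_kind == "sphere") return(spec$size)
  2 * (3 * spec$size * 1000 / (4 * pi))^(1 / 3)
}

## ---- rasterisation -------------------------------------------------------

# Fractional voxel coverage of an implicit solid: inside(x, y, z) -> logical.
# Supersamples each voxel with ns^3 midpoint subcells.
coverage_fraction <- function(grid, inside, ns = 4L) {
  cx <- grid_axis_coords(grid, 1)
  cy <- grid_axis_coords(grid, 2)
  cz <- grid_axis_coords(grid, 3)
  sub <- function(s) ((seq_len(ns) - 0.5) / ns - 0.5) * s
  cov <- array(0, grid$shape)
  for (dx in sub(grid$spacing[1]))
    for (dy in sub(grid$spacing[2]))
      for (dz in sub(grid$spacing[3]))
        cov <- cov + inside(cx + dx, cy + dy, cz + dz)
  cov / ns^3
}

# Binarise a coverage array so that the voxel volume best matches the target
# continuous volume: start from coverage >= 0.5, then swap boundary voxels in
# coverage order until no swap improves the volume error. Deterministic
# (ties resolved by linear index through order()'s stable sort).
binarise_volume_matched <- function(cov, grid, target_volume_mm3) {
  vv <- voxel_volume(grid)
  mask <- cov >= 0.5
  err <- function(n) abs(n * vv - target_volume_mm3)
  n <- sum(mask)
  if (n * vv < target_volume_mm3) {
    cand <- which(!mask & cov > 0)
    cand <- cand[order(cov[cand], decreasing = TRUE)]
    add <- 0L
    while (add < length(cand) && err(n + add + 1L) < err(n + add)) add <- add + 1L
    if (add > 0L) mask[cand[seq_len(add)]] <- TRUE
  } else {
    cand <- which(mask)
    cand <- cand[order(cov[cand])]
    drop <- 0L
    while (drop < length(cand) && err(n - drop - 1L) < err(n - drop)) drop <- drop + 1L
    if (drop > 0L) mask[cand[seq_len(drop)]] <- FALSE
  }
  mask
}

rasterise_ellipsoid <- function(grid, centre, semi_axes, volume_match = TRUE) {
  inside <- function(x, y, z) {
    outer(outer(((x - centre[1]) / semi_axes[1])^2,
                ((y - centre[2]) / semi_axes[2])^2, "+"),
          ((z - centre[3]) / semi_axes[3])^2, "+") <= 1
  }
  cov <- coverage_fraction(grid, inside)
  if (volume_match) {
    target <- 4 / 3 * pi * prod(semi_axes)
    binarise_volume_matched(cov, grid, target)
  } else cov >= 0.5
}

## ---- background ----------------------------------------------------------

#' Build a structured background uptake template
#'
#' Produces an uptake template with relative activity 1.0 everywhere except
#' inside the supplied ellipsoidal structures, which take their stated level.
#' Later structures override earlier ones where they overlap (a warning is
#' issued).
#'
#' @param grid a `grid_spec` (the fine template grid; 1 x 1 x 2 mm default
#'   elsewhere in the package).
#' @param structures list of structures, each a list with elements `centre`
#'   (mm), `semi_axes` (mm, length 3) and `level` (> 0 relative uptake).
#' @return An `uptake_template` with an empty lesion mask.
#' @examples
#' g <- grid_spec(c(40, 40, 20), c(1, 1, 2))
#' bg <- make_background(g, list(list(centre = c(10, 10, 10),
#'                                    semi_axes = c(6, 5, 5), level = 0.5)))
#' @export
make_background <- function(grid, structures = list()) {
  stopifnot_grid(grid)
  values <- array(1.0, grid$shape)
  occupied <- array(FALSE, grid$shape)
  for (st in structures) {
    if (is.null(st$level) || st$level <= 0)
      stop("make_background: structure levels must be > 0")
    m <- rasterise_ellipsoid(grid, st$centre, st$semi_axes,
                             volume_match = FALSE)
    if (any(m & occupied))
      warning("make_background: overlapping structures; later level wins")
    values[m] <- st$level
    occupied <- occupied | m
  }
  uptake_template(grid, values,
                  lesion_mask = binary_mask(array(FALSE, grid$shape), grid),
                  lesion_spec = NULL)
}

#' Uptake template container
#'
#' @param grid a `grid_spec`.
#' @param values 3-D non-negative array of relative activity.
#' @param lesion_mask `binary_mask` of the delivered ground-truth lesion.
#' @param lesion_spec the `lesion_spec` that produced it (or `NULL`).
#' @param core_mask optional `binary_mask` of a necrotic core.
#' @param outer_mask optional `binary_mask` of the full outer lesion shape
#'   (necrotic lesions: ground truth excludes the core, the full shape is
#'   retained here for sensitivity analyses).
#' @return An object of class `uptake_template`.
#' @export
uptake_template <- function(grid, values, lesion_mask, lesion_spec = NULL,
                            core_mask = NULL, outer_mask = NULL) {
  stopifnot_grid(grid)
  if (!all(dim(values) == grid$shape))
    stop("uptake_template: values shape does not match grid")
  if (any(values < 0)) stop("uptake_template: values must be >= 0")
  structure(list(grid = grid, values = values, lesion_mask = lesion_mask,
                 lesion_spec = lesion_spec, core_mask = core_mask,
                 outer_mask = outer_mask),
            class = "uptake_template")
}

#' @export
print.uptake_template <- function(x, ...) {
  cat(sprintf("<uptake_template> %s voxels; lesion: %s\n",
              paste(x$grid$shape, collapse = " x "),
              if (any(x$lesion_mask$voxels))
                sprintf("%s %s (%.2f mL)", x$lesion_spec$shape_kind,
                        x$lesion_spec$pattern, mask_volume_ml(x$lesion_mask))
              else "none"))
  invisible(x)
}

## ---- lesion insertion ----------------------------------------------------

#' Insert a lesion into a background template
#'
#' Rasterises the lesion shape on the template grid and writes its uptake
#' pattern over the background. Absolute levels follow the TBR convention:
#' with local background level B, the homogeneous lesion level is `tbr * B`;
#' the two-level pattern uses low level `L = tbr * B` in the rim and high
#' level `H = 2 L - B` in a concentric centre, so that `H - L = L - B`.
#' Necrotic patterns print zero activity in the core; the delivered
#' ground-truth mask excludes the core (the full outer shape is retained in
#' the returned template's `outer_mask`).
#'
#' @param background an `uptake_template`, typically from [make_background()].
#' @param spec a [lesion_spec()].
#' @param clearance_mm minimum required distance from the lesion to the grid
#'   edge (default 10).
#' @return A new `uptake_template` with `lesion_mask` (and, for necrotic
#'   patterns, `core_mask` and `outer_mask`) set.
#' @export
make_lesion_template <- function(background, spec, clearance_mm = 10) {
  if (!inherits(background, "uptake_template"))
    stop("make_lesion_template: background must be an uptake_template")
  if (!inherits(spec, "lesion_spec"))
    stop("make_lesion_template: spec must be a lesion_spec")
  grid <- background$grid
  radius <- equivalent_diameter_mm(spec) / 2

  lo <- grid$origin - grid$spacing / 2
  hi <- grid$origin + (grid$shape - 0.5) * grid$spacing
  if (any(spec$centre - radius - clearance_mm < lo) ||
      any(spec$centre + radius + clearance_mm > hi))
    stop("make_lesion_template: lesion does not fit with ",
         clearance_mm, " mm clearance to the grid edge")

  shapes <- rasterise_lesion_shape(grid, spec)
  outer_mask <- shapes$outer
  if (!any(outer_mask)) stop("make_lesion_template: empty lesion raster")

  values <- background$values
  B <- stats::median(values[outer_mask])   # local background level
  L <- spec$tbr * B
  H <- 2 * L - B

  pat <- spec$pattern
  if (pat == "homogeneous") {
    values[outer_mask] <- L
  } else if (pat == "two_level") {
    values[outer_mask] <- L
    values[shapes$inner] <- H
  } else if (pat == "gaussian") {
    excess <- array(0, grid$shape)
    excess[outer_mask] <- L - B
    fwhm <- if (is.null(spec$smooth_fwhm_mm))
      equivalent_diameter_mm(spec) / 2 else spec$smooth_fwhm_mm
    values <- values + gaussian_blur_3d(excess, fwhm, grid$spacing)
  } else if (pat %in% c("necrotic", "necrotic_gaussian")) {
    if (sum(shapes$core) >= sum(outer_mask))
      stop("make_lesion_template: necrotic core larger than lesion")
    if (pat == "necrotic") {
      values[outer_mask] <- L
      values[shapes$core] <- 0
    } else {
      # smooth the excess over background, keeping the background untouched
      excess <- array(0, grid$shape)
      excess[outer_mask] <- L - B
      excess[shapes$core] <- -B           # core prints zero activity
      fwhm <- if (is.null(spec$smooth_fwhm_mm))
        equivalent_diameter_mm(spec) / 2 else spec$smooth_fwhm_mm
      values <- pmax(values + gaussian_blur_3d(excess, fwhm, grid$spacing), 0)
    }
  }

  truth <- outer_mask
  core_mask <- NULL
  if (pat %in% c("necrotic", "necrotic_gaussian")) {
    truth <- outer_mask & !shapes$core
    core_mask <- binary_mask(shapes$core, grid)
  }
  uptake_template(grid, values,
                  lesion_mask = binary_mask(truth, grid),
                  lesion_spec = spec,
                  core_mask = core_mask,
                  outer_mask = binary_mask(outer_mask, grid))
}

# Rasterise the outer shape plus any inner (two-level) or core (necrotic)
# companion region for a lesion spec. Returns logical arrays.
rasterise_lesion_shape <- function(grid, spec) {
  kind <- spec$shape_kind
  inner <- core <- NULL
  if (kind == "sphere") {
    r <- spec$size / 2
    outer <- rasterise_ellipsoid(grid, spec$centre, rep(r, 3))
    if (spec$pattern == "two_level")
      inner <- rasterise_ellipsoid(grid, spec$centre,
                                   rep(r * spec$inner_fraction, 3))
    if (spec$pattern %in% c("necrotic", "necrotic_gaussian"))
      core <- rasterise_ellipsoid(grid, spec$centre,
                                  rep(r * spec$core_fraction^(1 / 3), 3))
  } else if (kind == "spheroid") {
    ax <- c(1.25, 1.0, 0.8)                 # fixed axis ratios
    s <- (spec$size * 1000 / (4 / 3 * pi * prod(ax)))^(1 / 3)
    semi <- ax * s
    outer <- rasterise_ellipsoid(grid, spec$centre, semi)
    if (spec$pattern == "two_level")
      inner <- rasterise_ellipsoid(grid, spec$centre,
                                   semi * spec$inner_fraction)
    if (spec$pattern %in% c("necrotic", "necrotic_gaussian"))
      core <- rasterise_ellipsoid(grid, spec$centre,
                                  semi * spec$core_fraction^(1 / 3))
  } else {
    sh <- irregular_radial_shape(spec$shape_seed)
    outer <- rasterise_radial_shape(grid, spec$centre, sh,
                                    spec$size * 1000)
    if (spec$pattern == "two_level")
      outer_scaled <- spec$size * spec$inner_fraction^3
    if (spec$pattern == "two_level")
      inner <- rasterise_radial_shape(grid, spec$centre, sh,
                                      outer_scaled * 1000)
    if (spec$pattern %in% c("necrotic", "necrotic_gaussian"))
      core <- rasterise_radial_shape(grid, spec$centre, sh,
                                     spec$size * spec$core_fraction * 1000)
  }
  list(outer = outer, inner = inner, core = core)
}
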