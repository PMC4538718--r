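# Procedural irregular lesion shapes: a seeded spherical-harmonic radial
# perturbation of the unit sphere, volume-rescaled to a target. Stands in for
# a manually delineated clinical head-and-neck tumour outline, which is not
# reproducible; shapes are star-convex about their centre but clearly
# non-spherical and non-convex.

# Real spherical harmonic basis values on a (theta, phi) lookup grid.
# Degrees 1..lmax, all orders; returns a list with the radius lookup table.
irregular_radial_shape <- function(shape_seed, lmax = 4L, amplitude = 0.3,
                                   n_theta = 181L, n_phi = 361L) {
  theta <- seq(0, pi, length.out = n_theta)
  phi <- seq(-pi, pi, length.out = n_phi)
  ct <- cos(theta)
  # draw coefficients deterministically from the seed
  coefs <- withr::with_seed(as.integer(shape_seed), {
    lapply(seq_len(lmax), function(l)
      stats::rnorm(2L * l + 1L, sd = amplitude / l))
  })
  r_theta_phi <- matrix(1, n_theta, n_phi)
  for (l in seq_len(lmax)) {
    P <- pracma::legendre(l, ct)            # (l+1) x n_theta, orders m = 0..l
    cl <- coefs[[l]]
    for (m in 0:l) {
      Nlm <- sqrt((2 * l + 1) / (4 * pi) *
                    factorial(l - m) / factorial(l + m))
      Plm <- P[m + 1L, ]
      if (m == 0) {
        r_theta_phi <- r_theta_phi +
          cl[1L] * Nlm * outer(Plm, rep(1, n_phi))
      } else {
        Nlm <- Nlm * sqrt(2)
        r_theta_phi <- r_theta_phi +
          cl[2L * m] * Nlm * outer(Plm, cos(m * phi)) +
          cl[2L * m + 1L] * Nlm * outer(Plm, sin(m * phi))
      }
    }
  }
  r_theta_phi <- pmax(r_theta_phi, 0.25)
  list(theta = theta, phi = phi, radius = r_theta_phi, seed = shape_seed)
}

# Volume (mm^3) and surface area (mm^2) of the continuous radial shape with
# radius lookup scaled by `scale`, by numerical integration over the sphere.
radial_shape_measures <- function(shape, scale = 1) {
  r <- shape$radius * scale
  th <- shape$theta; ph <- shape$phi
  dth <- th[2] - th[1]; dph <- ph[2] - ph[1]
  sin_th <- sin(th)
  # V = 1/3 * integral r^3 dOmega
  V <- sum(r[-1, -1]^3 * sin_th[-1]) * dth * dph / 3
  # dA = r * sqrt(r^2 + r_theta^2 + (r_phi / sin(theta))^2) sin(theta)
  r_th <- (r[c(2:nrow(r), nrow(r)), ] - r[c(1, 1:(nrow(r) - 1)), ]) /
    (2 * dth)
  r_ph <- (r[, c(2:ncol(r), ncol(r))] - r[, c(1, 1:(ncol(r) - 1))]) /
    (2 * dph)
  sin_safe <- pmax(sin_th, 1e-9)
  integrand <- r * sqrt(r^2 + r_th^2 + (r_ph / sin_safe)^2) * sin_th
  A <- sum(integrand[-1, -1]) * dth * dph
  list(volume = V, area = A,
       sphericity = pi^(1 / 3) * (6 * V)^(2 / 3) / A)
}

# Rasterise a radial shape at a centre, scaled so the continuous volume equals
# target_volume_mm3, on the sub-box of `grid` covering the shape.
rasterise_radial_shape <- function(grid, centre, shape, target_volume_mm3) {
  base <- radial_shape_measures(shape, 1)
  scale <- (target_volume_mm3 / base$volume)^(1 / 3)
  rmax <- max(shape$radius) * scale
  cx <- grid_axis_coords(grid, 1); cy <- grid_axis_coords(grid, 2)
  cz <- grid_axis_coords(grid, 3)
  ix <- which(abs(cx - centre[1]) <= rmax + grid$spacing[1])
  iy <- which(abs(cy - centre[2]) <= rmax + grid$spacing[2])
  iz <- which(abs(cz - centre[3]) <= rmax + grid$spacing[3])
  if (!length(ix) || !length(iy) || !length(iz))
    stop("rasterise_radial_shape: shape falls outside the grid")
  nb <- c(length(ix), length(iy), length(iz))
  ns <- 4L
  sub <- function(s) ((seq_len(ns) - 0.5) / ns - 0.5) * s
  n_th <- length(shape$theta); n_ph <- length(shape$phi)
  cov <- array(0, nb)
  for (dx in sub(grid$spacing[1]))
    for (dy in sub(grid$spacing[2]))
      for (dz in sub(grid$spacing[3])) {
        X <- array(cx[ix] + dx - centre[1], nb)
        Y <- aperm(array(cy[iy] + dy - centre[2], nb[c(2, 1, 3)]), c(2, 1, 3))
        Z <- aperm(array(cz[iz] + dz - centre[3], nb[c(3, 1, 2)]), c(2, 3, 1))
        rr <- sqrt(X^2 + Y^2 + Z^2)
        th <- acos(pmin(pmax(Z / pmax(rr, 1e-12), -1), 1))
        phv <- atan2(Y, X)
        it <- pmin(pmax(round(th / pi * (n_th - 1)) + 1, 1), n_th)
        ip <- pmin(pmax(round((phv + pi) / (2 * pi) * (n_ph - 1)) + 1, 1),
                   n_ph)
        rlim <- shape$radius[cbind(c(it), c(ip))] * scale
        cov <- cov + (c(rr) <= rlim)
      }
  cov <- cov / ns^3
  sub_grid <- grid_spec(nb, grid$spacing,
                        c(cx[ix[1]], cy[iy[1]], cz[iz[1]]))
  m_sub <- binarise_volume_matched(cov, sub_grid, target_volume_mm3)
  full <- array(FALSE, grid$shape)
  full[ix, iy, iz] <- m_sub
  full
}

#' Generate a connected irregular lesion mask
#'
#' Seeded spherical-harmonic radial perturbation (degrees 1-4) of a sphere,
#' rescaled so the rasterised volume matches `target_volume_ml`. The result
#' is deterministic for a fixed seed. The returned mask carries the analytic
#' volume, surface area and sphericity of the continuous shape as attributes
#' (`"analytic_volume_ml"`, `"analytic_area_mm2"`, `"sphericity"`).
#'
#' @param grid a `grid_spec`.
#' @param target_volume_ml target volume in mL.
#' @param shape_seed integer seed controlling the shape.
#' @param centre mm world coordinates of the shape centre; defaults to the
#'   grid centre.
#' @return A [binary_mask()].
#' @examples
#' g <- grid_spec(c(60, 60, 30), c(1, 1, 2), origin = c(-29.5, -29.5, -29))
#' m <- make_irregular_shape(g, 11, shape_seed = 1)
#' mask_volume_ml(m)
#' attr(m, "sphericity")
#' @export
make_irregular_shape <- function(grid, target_volume_ml, shape_seed = 1L,
                                 centre = NULL) {
  stopifnot_grid(grid)
  if (target_volume_ml <= 0)
    stop("make_irregular_shape: target volume must be > 0")
  if (is.null(centre))
    centre <- grid$origin + (grid$shape - 1) * grid$spacing / 2
  sh <- irregular_radial_shape(shape_seed)
  vox <- rasterise_radial_shape(grid, centre, sh, target_volume_ml * 1000)
  got <- sum(vox) * voxel_volume(grid) / 1000
  if (abs(got - target_volume_ml) / target_volume_ml > 0.05)
    stop(sprintf(paste0("make_irregular_shape: rasterised volume %.2f mL is ",
                        "not within 5%% of target %.2f mL; the grid is too ",
                        "coarse for this volume"), got, target_volume_ml))
  vox <- largest_component(vox)
  meas <- radial_shape_measures(
    sh, (target_volume_ml * 1000 / radial_shape_measures(sh, 1)$volume)^(1 / 3))
  out <- binary_mask(vox, grid)
  attr(out, "analytic_volume_ml") <- meas$volume / 1000
  attr(out, "analytic_area_mm2") <- meas$area
  attr(out, "sphericity") <- meas$sphericity
  out
}
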