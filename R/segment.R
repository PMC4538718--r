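#' Ten automatic PET segmentation methods behind one interface
#'
#' [segment_lesion()] dispatches on a method name: `"AT"` (3-D iterative
#' background-subtracted thresholding), `"RG"` (3-D iterative region growing
#' with automatic seed finder), `"GCM2"` .. `"GCM8"` (3-D fuzzy C-means on
#' voxel intensities with Gaussian-mixture variance weighting, identifying
#' the lowest-intensity cluster as background) and `"WT"` (slice-by-slice
#' marker-based watershed on the gradient magnitude).
#'
#' @param roi_image a `pet_image`, already cropped to the 10-mm-margin
#'   region of interest (see [crop_roi()]).
#' @param method one of `"AT"`, `"RG"`, `"GCM2"`..`"GCM8"`, `"WT"`.
#' @param params named list overriding the method defaults (see
#'   [default_method_params()]).
#' @param seed integer seed for any stochastic initialisation (the default
#'   initialisations are deterministic; the seed is kept for reproducibility
#'   of optional random restarts).
#' @return A `segmentation_result`: list with `mask` (a `binary_mask` on the
#'   ROI grid), `method`, `n_iterations`, `converged` and `diagnostics`.
#' @export
segment_lesion <- function(roi_image, method, params = list(), seed = 1L) {
  if (!inherits(roi_image, "pet_image"))
    stop("segment_lesion: roi_image must be a pet_image")
  method <- toupper(method)
  p <- utils::modifyList(default_method_params(method), params)
  res <- switch(sub("[0-9]+$", "", method),
                AT = segment_AT(roi_image, p),
                RG = segment_RG(roi_image, p),
                GCM = segment_GCM(roi_image,
                                  k = as.integer(sub("^GCM", "", method)),
                                  p, seed = seed),
                WT = segment_WT(roi_image, p),
                stop("segment_lesion: unknown method ", method))
  res$method <- method
  class(res) <- "segmentation_result"
  res
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %s: %d voxels, %s after %d iterations\n",
              x$method, sum(x$mask$voxels),
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  invisible(x)
}

#' Default tunable parameters per method family
#'
#' @param method a method name as in [segment_lesion()].
#' @return Named list of defaults. AT: `beta` (background-subtracted
#'   threshold fraction), `tol` (relative threshold tolerance), `max_iter`.
#'   RG: `alpha_schedule` (decreasing acceptance fractions), `min_region`
#'   (smallest region eligible for the plateau rule), `fill_holes`.
#'   GCM: `fuzziness`, `tol`, `max_iter`. WT: `smooth_sigma_mm` (gradient
#'   pre-smoothing), `marker_fraction` (intensity fraction separating
#'   internal from background markers), `min_basin_area` (pixels).
#' @export
default_method_params <- function(method) {
  fam <- sub("[0-9]+$", "", toupper(method))
  switch(fam,
         AT = list(beta = 0.8, tol = 1e-4, max_iter = 100L),
         RG = list(alpha_schedule = seq(0.95, 0.05, by = -0.05),
                   min_region = 8L, fill_holes = TRUE),
         GCM = list(fuzziness = 2, tol = 1e-8, max_iter = 1000L),
         WT = list(smooth_sigma_mm = 0, marker_fraction = 0.5,
                   min_basin_area = 1L),
         stop("default_method_params: unknown method ", method))
}

#' Automatic seed voxel finder
#'
#' Returns the voxel index (length-3 integer) of the maximum of the image
#' after a 3x3x3 mean smoothing (noise robustness). Smoothing plateaus are
#' resolved to the voxel with the highest raw intensity (so an isolated hot
#' voxel is returned itself, not a neighbour of equal smoothed value), and
#' remaining ties to the lowest linear index.
#'
#' @param roi_image a `pet_image`.
#' @export
find_seed <- function(roi_image) {
  v <- roi_image$values
  if (max(v) - min(v) <= 0)
    stop("find_seed: constant image has no meaningful maximum")
  sm <- box_mean_3x3x3(v)
  cands <- which(sm >= max(sm) - 1e-12 * max(abs(sm)))
  best <- cands[which.max(v[cands])]
  as.integer(arrayInd(best, dim(v)))
}

#' Background intensity estimate from the ROI shell
#'
#' Mean intensity of the one-voxel-thick outer shell of the ROI box. The 10
#' mm cropping margin guarantees the shell is background for interior
#' lesions.
#'
#' @param roi_image a `pet_image` with all dimensions >= 3.
#' @export
estimate_background <- function(roi_image) {
  d <- dim(roi_image$values)
  if (any(d < 3L))
    stop("estimate_background: ROI too small for a shell (all dims >= 3)")
  v <- roi_image$values
  inner <- v[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)]
  (sum(v) - sum(inner)) / (length(v) - length(inner))
}

## ---- AT: adaptive iterative background-subtracted thresholding -----------

segment_AT <- function(roi, p) {
  v <- roi$values
  bg <- estimate_background(roi)
  mx <- max(v)
  empty <- function(conv, it, thr) {
    list(mask = binary_mask(array(FALSE, dim(v)), roi$grid),
         n_iterations = it, converged = conv,
         diagnostics = list(threshold = thr, background = bg))
  }
  if (mx - bg <= 1e-12 * max(mx, 1)) return(empty(FALSE, 0L, NA_real_))
  thr <- bg + 0.5 * (mx - bg)
  mask <- v >= thr
  converged <- FALSE
  it <- 0L
  while (it < p$max_iter) {
    it <- it + 1L
    thr_new <- bg + p$beta * (mean(v[mask]) - bg)
    mask_new <- v >= thr_new
    if (identical(mask_new, mask) ||
        abs(thr_new - thr) < p$tol * mx) {
      mask <- mask_new; thr <- thr_new; converged <- TRUE
      break
    }
    mask <- mask_new; thr <- thr_new
  }
  if (!any(mask)) return(empty(converged, it, thr))
  mask <- largest_component(mask, 26L)
  list(mask = binary_mask(mask, roi$grid), n_iterations = it,
       converged = converged,
       diagnostics = list(threshold = thr, background = bg))
}

## ---- RG: iterative region growing with plateau selection -----------------

# Grow a 26-connected region from `seed_lin` accepting candidates with
# intensity >= alpha * mean(region), sweeping until stable.
grow_region <- function(v, d, nb, seed_lin, alpha) {
  region <- array(FALSE, d)
  region[seed_lin] <- TRUE
  pool <- integer(0)
  frontier <- seed_lin
  coord <- function(idx) {
    i0 <- idx - 1L
    cbind(i0 %% d[1], (i0 %/% d[1]) %% d[2], i0 %/% (d[1] * d[2]))
  }
  expand <- function(front) {
    if (!length(front)) return(integer(0))
    fc <- coord(front)
    cand <- integer(0)
    for (s in seq_len(nrow(nb$steps))) {
      st <- nb$steps[s, ]
      ok <- fc[, 1] + st[1] >= 0 & fc[, 1] + st[1] < d[1] &
            fc[, 2] + st[2] >= 0 & fc[, 2] + st[2] < d[2] &
            fc[, 3] + st[3] >= 0 & fc[, 3] + st[3] < d[3]
      if (!any(ok)) next
      cand <- c(cand, front[ok] + sum(st * nb$strides))
    }
    unique(cand)
  }
  pool <- setdiff(expand(frontier), seed_lin)
  vsum <- v[seed_lin]; n <- 1L
  repeat {
    if (!length(pool)) break
    thr <- alpha * (vsum / n)
    accept <- pool[v[pool] >= thr]
    if (!length(accept)) break
    region[accept] <- TRUE
    vsum <- vsum + sum(v[accept]); n <- n + length(accept)
    grown <- expand(accept)
    pool <- setdiff(unique(c(pool, grown)), c(accept, which(region)[0L]))
    pool <- pool[!region[pool]]
  }
  region
}

touches_border <- function(mask) {
  d <- dim(mask)
  any(mask[c(1, d[1]), , ]) || any(mask[, c(1, d[2]), ]) ||
    any(mask[, , c(1, d[3])])
}

segment_RG <- function(roi, p) {
  v <- roi$values
  d <- dim(v)
  nb <- neighbour_offsets(d, 26L)
  seed <- find_seed(roi)
  seed_lin <- seed[1] + (seed[2] - 1L) * d[1] + (seed[3] - 1L) * d[1] * d[2]
  alphas <- p$alpha_schedule
  vols <- numeric(length(alphas))
  regions <- vector("list", length(alphas))
  for (j in seq_along(alphas)) {
    regions[[j]] <- grow_region(v, d, nb, seed_lin, alphas[j])
    vols[j] <- sum(regions[[j]])
  }
  # plateau rule: select the acceptance fraction at the maximal relative
  # drop in region-volume growth, i.e. where the expansion per alpha step
  # decelerates the most (the onset of a growth plateau after an uptake
  # level has been absorbed). Leaked regions (touching the ROI border) and
  # regions too small for growth rates to be meaningful are not candidates;
  # ties resolve to the largest alpha (most conservative).
  m_steps <- length(vols)
  growth <- diff(vols) / pmax(vols[-m_steps], 1)
  decel <- c(-Inf, growth[-length(growth)] - growth[-1L])
  border <- vapply(regions, touches_border, logical(1))
  cand <- which(vols[seq_len(m_steps - 1L)] >= p$min_region &
                  !border[seq_len(m_steps - 1L)])
  j_star <- if (length(cand)) cand[which.max(decel[cand])]
    else if (any(!border)) max(which(!border)) else m_steps
  mask <- regions[[j_star]]
  converged <- !all(border)
  if (p$fill_holes && any(mask)) mask <- fill_holes_slicewise(mask)
  list(mask = binary_mask(mask, roi$grid), n_iterations = length(alphas),
       converged = converged,
       diagnostics = list(seed = seed, alpha = alphas[j_star],
                          volumes = stats::setNames(vols, alphas)))
}

## ---- GCM: fuzzy C-means with Gaussian variance weighting -----------------

segment_GCM <- function(roi, k, p, seed = 1L) {
  if (k < 2L || k > 8L) stop("segment_GCM: k must be in 2..8")
  x <- as.numeric(roi$values)
  rng <- max(x) - min(x)
  if (rng <= 0) stop("segment_GCM: constant image cannot be clustered")
  # aggregate over the (quantised) intensity histogram: identical fit,
  # one weighted observation per distinct intensity
  ux <- sort(unique(x))
  wx <- tabulate(match(x, ux))
  # hierarchical initialisation: fit 2 classes from range-spaced centres,
  # then grow one class at a time by splitting the most dispersed class and
  # warm-starting from the previous solution, so successive k are
  # continuations of one another
  fit <- gcm_fit(ux, 2L, m = p$fuzziness, tol = p$tol,
                 max_iter = p$max_iter, w = wx,
                 centres = min(x) + c(0.25, 0.75) * rng)
  kk <- 2L
  while (kk < k) {
    um <- fit$memberships^p$fuzziness * wx
    disp <- colSums(um * (matrix(ux, length(ux), kk) -
                            rep(fit$centres, each = length(ux)))^2)
    js <- which.max(disp)
    sd_j <- sqrt(fit$sigma2[js])
    centres <- sort(c(fit$centres[-js],
                      fit$centres[js] - sd_j / 2, fit$centres[js] + sd_j / 2))
    sigma2 <- rep(mean(fit$sigma2), kk + 1L)
    kk <- kk + 1L
    fit <- gcm_fit(ux, kk, m = p$fuzziness, tol = p$tol,
                   max_iter = p$max_iter, w = wx,
                   centres = centres, sigma2 = sigma2)
  }
  labels_x <- fit$labels[match(x, ux)]
  if (any(tabulate(labels_x, k) == 0L)) {
    # one deterministic re-initialisation from intensity quantiles
    fit <- gcm_fit(ux, k, m = p$fuzziness, tol = p$tol,
                   max_iter = p$max_iter, w = wx,
                   centres = unname(stats::quantile(
                     x, probs = (seq_len(k) - 0.5) / k)))
    labels_x <- fit$labels[match(x, ux)]
    if (any(tabulate(labels_x, k) == 0L))
      stop("segment_GCM: empty cluster after re-initialisation")
  }
  bg_cluster <- which.min(fit$centres)
  tumour <- array(labels_x != bg_cluster, dim(roi$values))
  if (any(tumour)) {
    tumour <- largest_component(tumour, 26L)
    tumour <- fill_holes_slicewise(tumour)
  }
  list(mask = binary_mask(tumour, roi$grid), n_iterations = fit$iterations,
       converged = fit$converged,
       diagnostics = list(cluster_means = fit$centres,
                          cluster_sds = sqrt(fit$sigma2),
                          background_cluster = bg_cluster))
}

# Fuzzy C-means on 1-D intensities coupled to Gaussian class models:
# memberships are fuzzified Gaussian log-densities (class mean and variance
# re-estimated from the fuzzy weights each sweep), raised to 1/(m-1) and
# normalised. The -log(sigma) normalisation term lets a narrow, dominant
# background class keep its members, which plain variance-scaled distances
# do not; class weights are deliberately uniform so sparse high-uptake
# classes are not starved.
gcm_fit <- function(x, k, m, tol, max_iter, centres, sigma2 = NULL,
                    w = NULL) {
  rng <- max(x) - min(x)
  n <- length(x)
  if (is.null(w)) w <- rep(1, n)
  if (is.null(sigma2)) sigma2 <- rep((rng / k)^2, k)
  sig_floor <- (1e-3 * rng)^2
  sigma2 <- pmax(sigma2, sig_floor)
  expo <- 1 / (m - 1)
  u <- matrix(0, n, k)
  iter <- 0L; converged <- FALSE
  repeat {
    iter <- iter + 1L
    loglik <- vapply(seq_len(k), function(j)
      -0.5 * log(2 * pi * sigma2[j]) -
        (x - centres[j])^2 / (2 * sigma2[j]),
      numeric(n))
    # fuzzified class responsibilities, computed stably in log space
    lw <- loglik * expo
    lw <- lw - apply(lw, 1, max)
    ew <- exp(lw)
    u <- ew / rowSums(ew)
    um <- u^m * w
    cs <- colSums(um)
    dead <- cs < 1e-10
    cs[dead] <- 1
    new_centres <- colSums(um * x) / cs
    new_centres[dead] <- centres[dead]     # keep a dead cluster in place
    sigma2 <- pmax(colSums(um * (x - rep(new_centres, each = n))^2) / cs,
                   sig_floor)
    delta <- max(abs(new_centres - centres))
    centres <- new_centres
    if (delta < tol * rng) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  list(labels = max.col(u, ties.method = "first"),
       centres = centres, sigma2 = sigma2, memberships = u,
       iterations = iter, converged = converged)
}

## ---- WT: slice-by-slice marker-based watershed ----------------------------

# Priority-flood watershed on a 2-D landscape from integer markers
# (0 = unlabelled). Equal priorities resolve first-in-first-out, so plateau
# pixels are claimed by the basin that reached them first.
marker_watershed_2d <- function(landscape, markers) {
  d <- dim(landscape)
  n <- prod(d)
  rank <- matrix(match(landscape, sort(unique(as.vector(landscape)))), d[1])
  lab <- markers
  key_base <- 16L * n + 1L
  # binary heap of (key, pixel, label)
  cap <- 16L * n
  hk <- numeric(cap); hp <- integer(cap); hl <- integer(cap)
  hn <- 0L; counter <- 0L
  push <- function(key, pix, l) {
    hn <<- hn + 1L
    i <- hn; hk[i] <<- key; hp[i] <<- pix; hl[i] <<- l
    while (i > 1L) {
      par <- i %/% 2L
      if (hk[par] <= hk[i]) break
      tmp <- hk[par]; hk[par] <<- hk[i]; hk[i] <<- tmp
      tmp <- hp[par]; hp[par] <<- hp[i]; hp[i] <<- tmp
      tmp <- hl[par]; hl[par] <<- hl[i]; hl[i] <<- tmp
      i <- par
    }
  }
  pop <- function() {
    out <- c(hp[1L], hl[1L])
    hk[1L] <<- hk[hn]; hp[1L] <<- hp[hn]; hl[1L] <<- hl[hn]
    hn <<- hn - 1L
    i <- 1L
    repeat {
      l <- 2L * i; r <- l + 1L; s <- i
      if (l <= hn && hk[l] < hk[s]) s <- l
      if (r <= hn && hk[r] < hk[s]) s <- r
      if (s == i) break
      tmp <- hk[s]; hk[s] <<- hk[i]; hk[i] <<- tmp
      tmp <- hp[s]; hp[s] <<- hp[i]; hp[i] <<- tmp
      tmp <- hl[s]; hl[s] <<- hl[i]; hl[i] <<- tmp
      i <- s
    }
    out
  }
  # 4-connected flood: diagonal steps would leak across one-pixel-thin
  # gradient ridges (cf. the connectivity-1 default of standard watershed
  # implementations)
  nb_off <- data.frame(dx = c(1L, -1L, 0L, 0L), dy = c(0L, 0L, 1L, -1L))
  # markers seed the flood at the lowest priority regardless of their own
  # altitude (their pixel is theirs by definition)
  for (pix in which(markers > 0L)) {
    counter <- counter + 1L
    push(counter, pix, markers[pix])
  }
  line_label <- 3L
  while (hn > 0L) {
    pl <- pop()
    pix <- pl[1L]
    if (lab[pix] > 0L && markers[pix] == 0L) next
    if (lab[pix] == 0L) {
      # Meyer's convention: a pixel reached by more than one basin is a
      # watershed-line pixel; it takes no basin and does not propagate
      x0 <- (pix - 1L) %% d[1]; y0 <- (pix - 1L) %/% d[1]
      seen <- integer(0)
      for (s in 1:4) {
        nx <- x0 + nb_off$dx[s]; ny <- y0 + nb_off$dy[s]
        if (nx < 0L || nx >= d[1] || ny < 0L || ny >= d[2]) next
        l <- lab[nx + ny * d[1] + 1L]
        if (l > 0L && l != line_label) seen <- c(seen, l)
      }
      u <- unique(seen)
      if (length(u) == 1L) lab[pix] <- u
      else if (length(u) > 1L) { lab[pix] <- line_label; next }
      else lab[pix] <- pl[2L]
    }
    x <- (pix - 1L) %% d[1]; y <- (pix - 1L) %/% d[1]
    for (s in seq_len(nrow(nb_off))) {
      nx <- x + nb_off$dx[s]; ny <- y + nb_off$dy[s]
      if (nx < 0L || nx >= d[1] || ny < 0L || ny >= d[2]) next
      np <- nx + ny * d[1] + 1L
      if (lab[np] > 0L) next
      counter <- counter + 1L
      push(rank[np] * key_base + counter, np, lab[pix])
    }
  }
  lab
}

# Central-difference gradient magnitude of a 2-D slice, spacing-aware.
gradient_magnitude_2d <- function(sl, spacing) {
  d <- dim(sl)
  gx <- (sl[c(2:d[1], d[1]), ] - sl[c(1, 1:(d[1] - 1)), ]) / (2 * spacing[1])
  gy <- (sl[, c(2:d[2], d[2])] - sl[, c(1, 1:(d[2] - 1))]) / (2 * spacing[2])
  sqrt(gx^2 + gy^2)
}

# Regional minima (<= all 8 neighbours) of a 2-D landscape.
regional_minima_2d <- function(g) {
  d <- dim(g)
  pad <- matrix(Inf, d[1] + 2, d[2] + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1)] <- g
  res <- matrix(TRUE, d[1], d[2])
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    res <- res & g <= pad[2:(d[1] + 1) + dx, 2:(d[2] + 1) + dy]
  }
  res
}

segment_WT <- function(roi, p) {
  v <- roi$values
  d <- dim(v)
  if (max(v) - min(v) <= 0) {
    return(list(mask = binary_mask(array(FALSE, d), roi$grid),
                n_iterations = 0L, converged = TRUE,
                diagnostics = list(slices_used = integer(0))))
  }
  bg <- estimate_background(roi)
  mx <- max(v)
  thr <- bg + p$marker_fraction * (mx - bg)
  mask <- array(FALSE, d)
  used <- integer(0)
  areas <- integer(0)
  for (k in seq_len(d[3])) {
    sl <- v[, , k, drop = TRUE]
    if (d[1] == 1 || d[2] == 1) next
    if (max(sl) < thr) next                       # no internal marker
    sm <- if (p$smooth_sigma_mm > 0) {
      a <- array(sl, c(d[1], d[2], 1))
      gaussian_blur_3d(a, p$smooth_sigma_mm * 2 * sqrt(2 * log(2)),
                       c(roi$grid$spacing[1:2], 1))[, , 1]
    } else sl
    g <- gradient_magnitude_2d(sm, roi$grid$spacing[1:2])
    markers <- matrix(0L, d[1], d[2])
    # background markers: slice border plus low-intensity regional minima
    markers[c(1, d[1]), ] <- 2L
    markers[, c(1, d[2])] <- 2L
    low_min <- regional_minima_2d(g) & sl < thr
    markers[low_min] <- 2L
    # internal marker: the maximum plateau of the slice (a single voxel for
    # smooth data; the full uniform disc for sharp two-valued slices)
    plateau <- array(sm >= max(sm), c(d[1], d[2], 1))
    comp <- label_components(plateau, 26L)[, , 1]
    markers[comp == comp[which.max(sm)]] <- 1L
    lab <- marker_watershed_2d(g, markers)
    basin <- lab == 1L
    if (sum(basin) < p$min_basin_area) next
    mask[, , k] <- basin
    used <- c(used, k)
    areas <- c(areas, sum(basin))
  }
  list(mask = binary_mask(mask, roi$grid), n_iterations = length(used),
       converged = length(used) > 0L,
       diagnostics = list(slices_used = used, basin_areas = areas,
                          marker_threshold = thr))
}
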