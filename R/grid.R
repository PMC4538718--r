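#' Voxel grid specification
#'
#' A `grid_spec` ties a 3-D array to physical space: `shape` voxels per axis,
#' `spacing` in mm per axis and `origin`, the mm world coordinate of the centre
#' of voxel (1,1,1). Voxel `i` (1-based) is centred at
#' `origin + (i - 1) * spacing` and covers the half-open interval of width
#' `spacing` around its centre.
#'
#' @param shape integer vector of length 3, voxel counts per axis (all >= 1).
#' @param spacing numeric vector of length 3, mm per voxel (all > 0).
#' @param origin numeric vector of length 3, mm coordinate of the first voxel
#'   centre. Defaults to `c(0, 0, 0)`.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(c(64, 64, 30), c(1, 1, 2))
#' voxel_volume(g)
#' @export
grid_spec <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || length(spacing) != 3L || length(origin) != 3L)
    stop("grid_spec: shape, spacing and origin must each have length 3")
  if (any(is.na(shape)) || any(shape < 1L))
    stop("grid_spec: all shape entries must be >= 1")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("grid_spec: all spacings must be > 0")
  if (any(!is.finite(origin)))
    stop("grid_spec: origin must be finite")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %s voxels, %s mm spacing, origin (%s) mm\n",
              paste(x$shape, collapse = " x "),
              paste(format(x$spacing, trim = TRUE), collapse = " x "),
              paste(format(x$origin, trim = TRUE), collapse = ", ")))
  invisible(x)
}

#' @rdname grid_spec
#' @param grid a `grid_spec`.
#' @export
voxel_volume <- function(grid) prod(grid$spacing)

#' Voxel-centre world coordinates along one axis
#'
#' @param grid a `grid_spec`.
#' @param axis axis index in 1:3.
#' @return Numeric vector of mm coordinates of the voxel centres.
#' @export
grid_axis_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing[axis]
}

#' Convert world mm coordinates to the nearest voxel index
#'
#' @param grid a `grid_spec`.
#' @param xyz numeric vector of length 3 (mm) or a 3-column matrix.
#' @return Integer voxel indices (1-based), clipped to the grid.
#' @export
world_to_index <- function(grid, xyz) {
  f <- function(p) pmin(pmax(as.integer(round((p - grid$origin) /
                                               grid$spacing)) + 1L, 1L),
                        grid$shape)
  if (is.matrix(xyz)) t(apply(xyz, 1, f)) else f(as.numeric(xyz))
}

#' @rdname world_to_index
#' @param ijk integer voxel indices (1-based), vector of length 3 or matrix.
#' @export
index_to_world <- function(grid, ijk) {
  f <- function(i) grid$origin + (as.numeric(i) - 1) * grid$spacing
  if (is.matrix(ijk)) t(apply(ijk, 1, f)) else f(ijk)
}

grids_identical <- function(a, b) {
  identical(a$shape, b$shape) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-12)) &&
    isTRUE(all.equal(a$origin, b$origin, tolerance = 1e-12))
}

stopifnot_grid <- function(grid) {
  if (!inherits(grid, "grid_spec")) stop("expected a grid_spec")
  invisible(grid)
}

#' Binary mask on a grid
#'
#' @param voxels 3-D logical array.
#' @param grid the `grid_spec` the mask lives on; shapes must agree.
#' @return An object of class `binary_mask` with elements `grid` and `voxels`.
#' @export
binary_mask <- function(voxels, grid) {
  stopifnot_grid(grid)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("binary_mask: voxels must be a 3-D array")
  if (!all(dim(voxels) == grid$shape))
    stop("binary_mask: voxel array shape does not match grid")
  storage.mode(voxels) <- "logical"
  structure(list(grid = grid, voxels = voxels), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d of %d voxels set (%.2f mL)\n",
              sum(x$voxels), length(x$voxels), mask_volume_ml(x)))
  invisible(x)
}

#' Mask volume in millilitres
#'
#' Voxel count times voxel volume, in mL (1 mL = 1000 mm^3).
#' @param mask a `binary_mask`.
#' @export
mask_volume_ml <- function(mask) {
  sum(mask$voxels) * voxel_volume(mask$grid) / 1000
}
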