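# File interfaces: NIfTI volumes (RNifti), YAML phantom/experiment
# descriptions. The affine is diagonal, built from the grid spacing with the
# origin in the translation column.

#' Write a volume to NIfTI
#'
#' Works for `uptake_template` values, `pet_image` and `binary_mask`
#' (written as 0/1). The grid's spacing and origin populate the sform/qform.
#'
#' @param x an `uptake_template`, `pet_image`, `binary_mask`, or a bare 3-D
#'   array (then `grid` must be given).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param grid `grid_spec`, only for bare arrays.
#' @return Invisibly, `path`.
#' @export
write_nifti_volume <- function(x, path, grid = NULL) {
  if (inherits(x, "uptake_template") || inherits(x, "pet_image")) {
    values <- x$values; grid <- x$grid
  } else if (inherits(x, "binary_mask")) {
    values <- array(as.numeric(x$voxels), dim(x$voxels)); grid <- x$grid
  } else {
    if (is.null(grid)) stop("write_nifti_volume: grid required for arrays")
    values <- x
  }
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- grid$spacing
  aff <- diag(c(grid$spacing, 1))
  aff[1:3, 4] <- grid$origin
  # sform only: assigning the qform as well recomputes the geometry from
  # unit pixdims on write and silently drops the spacing
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a PET image (or mask) from NIfTI
#'
#' @param path NIfTI file.
#' @param as `"image"` (default) or `"mask"` (values > 0.5 become TRUE).
#' @return A `pet_image` with provenance `"file"`, or a `binary_mask`.
#' @export
read_nifti_volume <- function(path, as = c("image", "mask")) {
  as <- match.arg(as)
  img <- RNifti::readNifti(path)
  values <- array(as.numeric(img), dim(img)[1:3])
  aff <- RNifti::xform(img)
  spacing <- abs(diag(aff)[1:3])
  origin <- aff[1:3, 4]
  grid <- grid_spec(dim(values), spacing, origin)
  if (as == "mask") binary_mask(values > 0.5, grid)
  else pet_image(pmax(values, 0), grid, provenance = "file")
}

#' Read and write experiment configurations as YAML
#'
#' @param config an `experiment_config` list (see [experiment_config()]).
#' @param path YAML file path.
#' @export
write_experiment_yaml <- function(config, path) {
  yaml::write_yaml(unclass_deep(config), path)
  invisible(path)
}

#' @rdname write_experiment_yaml
#' @export
read_experiment_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- experiment_config(
    lesions = lapply(raw$lesions, function(l) {
      l$spec <- do.call(lesion_spec, l$spec); l
    }),
    pet_spacing = as.numeric(raw$pet_spacing),
    psf_fwhm_mm = raw$psf_fwhm_mm,
    noise_scale = raw$noise_scale,
    noise_seeds = as.integer(raw$noise_seeds),
    noiseless = isTRUE(raw$noiseless),
    methods_sphere = raw$methods_sphere,
    methods_lesion = raw$methods_lesion)
  cfg
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, unclass_deep)
    attributes(x) <- list(names = names(x))
  }
  x
}
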