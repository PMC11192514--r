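#' Construct a binary volumetric mask
#'
#' A 3-D binary mask (lesion or atlas ROI) on a voxel grid with physical
#' voxel dimensions. Lesion and ROI masks to be compared must share grid
#' shape and space label.
#'
#' @param grid 3-D array with values in `{0, 1}` (logical allowed).
#' @param voxel_mm Length-3 numeric, voxel size in mm (all > 0).
#' @param space_label Free-text label of the reference space (e.g. an
#'   MNI-normalized template); defaults to `"native"`.
#' @return Object of class `binary_volume`.
#' @export
binary_volume <- function(grid, voxel_mm = c(1, 1, 1), space_label = "native") {
  if (!is.array(grid) || length(dim(grid)) != 3)
    stop("`grid` must be a 3-D array")
  g <- grid
  storage.mode(g) <- "integer"
  if (any(is.na(g)) || !all(g %in% c(0L, 1L)))
    stop("mask values must be 0/1")
  if (length(voxel_mm) != 3 || any(!is.finite(voxel_mm)) || any(voxel_mm <= 0))
    stop("`voxel_mm` must be 3 positive values")
  structure(list(grid = g, voxel_mm = as.numeric(voxel_mm),
                 space_label = space_label),
            class = "binary_volume")
}

#' @export
print.binary_volume <- function(x, ...) {
  cat(sprintf("<binary_volume> %s, %s voxels @ %s mm, %d set\n",
              x$space_label, paste(dim(x$grid), collapse = "x"),
              paste(x$voxel_mm, collapse = "x"), sum(x$grid)))
  invisible(x)
}

#' Lesion profile: total volume and percent spared per atlas ROI
#'
#' For each ROI, the lesion overlap is removed and the remaining voxel count
#' is divided by the ROI's total voxel count:
#' `percent_spared = 100 * |ROI \ lesion| / |ROI|`. Total lesion volume is
#' the lesion voxel count times the voxel volume, in mm^3. Masks are binary
#' and voxel counts are exact (no partial-volume weighting).
#'
#' @param lesion A [binary_volume()] lesion mask.
#' @param rois Named list of [binary_volume()] ROI masks on the same grid
#'   and in the same space.
#' @return List of class `lesion_profile`: `total_volume` (mm^3),
#'   `percent_spared` (named numeric in `[0, 100]`), `n_lesion_voxels`.
#' @export
lesion_profile <- function(lesion, rois) {
  stopifnot(inherits(lesion, "binary_volume"))
  if (length(rois) == 0 || is.null(names(rois)) || any(names(rois) == ""))
    stop("`rois` must be a non-empty named list")
  spared <- vapply(names(rois), function(nm) {
    r <- rois[[nm]]
    stopifnot(inherits(r, "binary_volume"))
    if (!identical(dim(r$grid), dim(lesion$grid)))
      stop(sprintf("ROI '%s' grid shape does not match lesion grid", nm))
    if (!identical(r$space_label, lesion$space_label))
      stop(sprintf("ROI '%s' space '%s' does not match lesion space '%s'",
                   nm, r$space_label, lesion$space_label))
    n_roi <- sum(r$grid)
    if (n_roi == 0) stop(sprintf("ROI '%s' is empty", nm))
    100 * sum(r$grid == 1L & lesion$grid == 0L) / n_roi
  }, numeric(1))
  n_les <- sum(lesion$grid)
  structure(list(total_volume = n_les * prod(lesion$voxel_mm),
                 percent_spared = spared, n_lesion_voxels = n_les),
            class = "lesion_profile")
}

#' @export
print.lesion_profile <- function(x, ...) {
  cat(sprintf("<lesion_profile> total volume %.0f mm^3 (%d voxels)\n",
              x$total_volume, x$n_lesion_voxels))
  for (nm in names(x$percent_spared))
    cat(sprintf("  %-12s %6.2f%% spared\n", nm, x$percent_spared[[nm]]))
  invisible(x)
}

#' Write a binary volume to a NIfTI file
#'
#' @param volume A [binary_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "binary_volume"))
  img <- RNifti::asNifti(volume$grid)
  RNifti::pixdim(img) <- volume$voxel_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary volume from a NIfTI file
#'
#' Values are binarized with a 0.5 threshold (masks written by
#' [write_volume_nifti()] round-trip exactly).
#'
#' @param path NIfTI file path.
#' @param space_label Space label to attach (default `"native"`).
#' @return A [binary_volume()].
#' @export
read_volume_nifti <- function(path, space_label = "native") {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[1:3]
  binary_volume(array(as.integer(img > 0.5), dim = dim(img)[1:3]),
                voxel_mm = vox, space_label = space_label)
}
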