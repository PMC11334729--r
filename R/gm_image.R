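#' Gray-matter image container
#'
#' A subject's 3D GM volume on a regular voxel grid. Values must be finite and
#' nonnegative; voxel size is isotropic in mm.
#'
#' @param values 3D numeric array of GM volume values (>= 0).
#' @param voxel_size_mm voxel edge length in mm.
#' @param subject_id subject identifier string.
#' @return An object of class \code{gm_image}.
#' @export
gm_image <- function(values, voxel_size_mm = 2, subject_id = "unknown") {
  if (length(dim(values)) != 3L) stopf("gm_image values must be a 3D array")
  if (!all(is.finite(values))) stopf("gm_image values must all be finite")
  if (min(values) < 0) stopf("gm_image values must be nonnegative")
  if (voxel_size_mm <= 0) stopf("voxel_size_mm must be positive")
  structure(list(values = values,
                 voxel_size_mm = voxel_size_mm,
                 subject_id = as.character(subject_id)),
            class = "gm_image")
}

#' @export
print.gm_image <- function(x, ...) {
  cat(sprintf("GM image '%s': %s voxels at %g mm, GM range [%.3g, %.3g]\n",
              x$subject_id, paste(dim(x$values), collapse = "x"),
              x$voxel_size_mm, min(x$values), max(x$values)))
  invisible(x)
}

#' Read / write GM volumes as NIfTI-1
#'
#' Round-trips values (float32 precision), shape, and voxel size through
#' NIfTI-1 files (optionally gzip-compressed, by extension).
#'
#' @param path file path (.nii or .nii.gz).
#' @param subject_id optional identifier; defaults to the file stem.
#' @return [read_gm_image()] returns a [gm_image()]; [write_gm_image()] returns
#'   the path invisibly.
#' @export
read_gm_image <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  nii <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stopf("malformed NIfTI file '%s': %s",
                                            path, conditionMessage(e)))
  if (is.null(subject_id)) {
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  vox <- RNifti::pixdim(nii)[1]
  gm_image(array(as.numeric(nii), dim(nii)[1:3]),
           voxel_size_mm = vox, subject_id = subject_id)
}

#' @rdname read_gm_image
#' @param image a [gm_image()].
#' @export
write_gm_image <- function(image, path) {
  nii <- RNifti::asNifti(image$values)
  RNifti::pixdim(nii) <- rep(image$voxel_size_mm, 3)
  RNifti::writeNifti(nii, path, datatype = "float")
  invisible(path)
}
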