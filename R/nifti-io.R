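#' Read a NIfTI-1 volume
#'
#' Loads a single-file NIfTI-1 image (`.nii` or `.nii.gz`) into a
#' [voxel_image()].  Spacing is taken from the header `pixdim`; the
#' voxel-to-world affine from the sform when its code is valid, otherwise the
#' qform (a warning is issued when both are valid but disagree).
#'
#' @param path path to a 3D NIfTI-1 file.
#' @return a `voxel_image`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  nii <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  hdr <- RNifti::niftiHeader(nii)
  nd <- hdr$dim[1]
  if (nd > 3L && any(hdr$dim[seq(5, 1 + nd)] > 1L))
    stop("'", path, "' is ", nd, "D; only 3D volumes are supported")
  arr <- as.array(nii)
  attributes(arr) <- list(dim = dim(arr)[1:3])
  sf <- hdr$sform_code > 0
  qf <- hdr$qform_code > 0
  if (sf) {
    aff <- rbind(hdr$srow_x, hdr$srow_y, hdr$srow_z, c(0, 0, 0, 1))
    if (qf) {
      qaff <- matrix(RNifti::xform(nii, useQuaternionFirst = TRUE), 4, 4)
      if (max(abs(qaff - aff)) > 1e-4)
        warning("sform and qform disagree in '", path, "'; using sform")
    }
  } else {
    aff <- matrix(RNifti::xform(nii, useQuaternionFirst = TRUE), 4, 4)
  }
  voxel_image(arr, spacing = hdr$pixdim[2:4], affine = aff)
}

#' Write a volume as NIfTI-1
#'
#' @param img a `voxel_image` or `binary_mask` (masks are written as uint8).
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param datatype NIfTI datatype string passed to RNifti (default `"double"`
#'   for images; masks always use `"uint8"`).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(img, path, datatype = "double") {
  dat <- img$data
  if (inherits(img, "binary_mask")) {
    storage.mode(dat) <- "integer"
    datatype <- "uint8"
  }
  nii <- RNifti::asNifti(structure(dat, pixdim = img$spacing),
                         datatype = datatype)
  aff <- structure(img$affine, code = 2L)
  nii <- RNifti::`sform<-`(nii, aff)
  nii <- RNifti::`qform<-`(nii, aff)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Write a deformation field as a vector NIfTI
#'
#' Stored as a 5D NIfTI (x, y, z, 1, 3) with the displacement intent code and
#' millimetre units, matching the convention used for displacement fields.
#'
#' @param field a `deformation_field`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_deformation <- function(field, path) {
  d <- dim(field$disp)
  arr <- array(field$disp, c(d[1:3], 1L, 3L))
  nii <- RNifti::asNifti(structure(arr, pixdim = c(field$spacing, 1, 1)),
                         datatype = "double")
  aff <- structure(field$affine, code = 2L)
  nii <- RNifti::`sform<-`(nii, aff)
  nii <- RNifti::`qform<-`(nii, aff)
  hdr <- RNifti::niftiHeader(nii)
  nii <- RNifti::asNifti(nii, intent_code = 1006L)  # NIFTI_INTENT_DISPVECT
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Read a deformation field written by [write_deformation()]
#' @param path path to a 5D displacement NIfTI.
#' @return a `deformation_field`.
#' @export
read_deformation <- function(path) {
  nii <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(nii)
  arr <- as.array(nii)
  d <- dim(arr)
  if (length(d) < 4L || d[length(d)] != 3L)
    stop("'", path, "' is not a 3-component vector field")
  arr <- array(arr, c(d[1:3], 3L))
  aff <- rbind(hdr$srow_x, hdr$srow_y, hdr$srow_z, c(0, 0, 0, 1))
  deformation_field(arr, spacing = hdr$pixdim[2:4], affine = aff)
}
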