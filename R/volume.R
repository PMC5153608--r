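#' @include AllClasses.R
NULL

#' Construct a PETVolume
#'
#' @param data 3-D numeric array of tracer uptake.
#' @param spacing numeric(3) voxel size in mm (default 2 mm isotropic, the
#'   working resolution assumed throughout).
#' @return A \linkS4class{PETVolume}.
#' @export
PETVolume <- function(data, spacing = c(2, 2, 2)) {
  if (is.null(dim(data)) || length(dim(data)) != 3L) {
    .err("error_notVolume", "data must be a 3-D array")
  }
  if (any(!is.finite(data))) {
    .err("error_nonfinite", "volume contains non-finite data")
  }
  new("PETVolume", data = array(as.double(data), dim(data)),
      spacing = as.double(spacing))
}

#' Construct a BrainMask
#'
#' @param data 3-D logical (or 0/1 numeric) array.
#' @param spacing numeric(3) voxel size in mm.
#' @return A \linkS4class{BrainMask}.
#' @export
BrainMask <- function(data, spacing = c(2, 2, 2)) {
  if (is.null(dim(data)) || length(dim(data)) != 3L) {
    .err("error_notVolume", "mask data must be a 3-D array")
  }
  m <- array(as.logical(data != 0), dim(data))
  if (!any(m)) .err("error_emptyMask", "mask has no TRUE voxels")
  new("BrainMask", data = m, spacing = as.double(spacing))
}

.niftiSpacing <- function(img) {
  pd <- RNifti::pixdim(img)
  as.double(pd[seq_len(3)])
}

#' Read a volume from a NIfTI-1 file
#'
#' Reads a 3-D NIfTI image, takes the voxel spacing from the header and
#' casts the data to double. Non-3-D images and non-finite voxels are
#' errors; anisotropic voxels are refused by default because the descriptor
#' assumes isotropic sampling (the field-standard preprocessing resamples to
#' 2 mm isotropic).
#'
#' @param path path to a .nii or .nii.gz file.
#' @param allowAnisotropic if TRUE, skip the isotropy check.
#' @return A \linkS4class{PETVolume}.
#' @export
readVolume <- function(path, allowAnisotropic = FALSE) {
  if (!file.exists(path)) {
    .err("error_missingFile", sprintf("file not found: %s", path))
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    .err("error_notVolume", sprintf("expected a 3-D image, got %d dimensions",
                                    length(d)))
  }
  dat <- array(as.double(img), d)
  if (any(!is.finite(dat))) {
    .err("error_nonfinite", "volume contains non-finite data")
  }
  sp <- .niftiSpacing(img)
  if (!allowAnisotropic && (max(sp) - min(sp)) > 1e-6 * max(sp)) {
    .err("error_anisotropic",
         sprintf("anisotropic voxels (%s mm); resample upstream or set allowAnisotropic=TRUE",
                 paste(format(sp), collapse = " x ")))
  }
  PETVolume(dat, sp)
}

#' Write a volume (or mask) to a NIfTI-1 file
#'
#' @param x a \linkS4class{PETVolume} or \linkS4class{BrainMask}.
#' @param path output path (.nii or .nii.gz).
#' @return invisibly, the path.
#' @export
writeVolume <- function(x, path) {
  if (is(x, "BrainMask")) {
    dat <- array(as.double(x@data), dim(x@data))
    sp <- x@spacing
  } else {
    dat <- x@data
    sp <- x@spacing
  }
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask from a NIfTI-1 file
#'
#' Any nonzero voxel is TRUE.
#'
#' @param path path to a .nii/.nii.gz file.
#' @return A \linkS4class{BrainMask}.
#' @export
readMask <- function(path) {
  v <- readVolume(path, allowAnisotropic = TRUE)
  BrainMask(v@data != 0, v@spacing)
}

.checkSameShape <- function(volume, mask) {
  if (!identical(dim(volume@data), dim(mask@data))) {
    .err("error_shapeMismatch", "volume and mask shapes differ")
  }
}

#' Zero a volume outside a mask
#'
#' @param volume a \linkS4class{PETVolume}.
#' @param mask a \linkS4class{BrainMask} of the same shape.
#' @return A \linkS4class{PETVolume} with voxels outside the mask set to 0.
#' @export
maskVolume <- function(volume, mask) {
  .checkSameShape(volume, mask)
  d <- volume@data
  d[!mask@data] <- 0
  PETVolume(d, volume@spacing)
}

# tight bounding box of TRUE voxels: list(lo = int(3), hi = int(3)), 1-based
.maskBoundingBox <- function(maskArr) {
  idx <- which(maskArr, arr.ind = TRUE)
  list(lo = as.integer(apply(idx, 2, min)), hi = as.integer(apply(idx, 2, max)))
}

#' Crop a volume to the bounding box of a mask
#'
#' Returns the sub-volume spanned by the tight bounding box of TRUE mask
#' voxels; voxels inside the box but outside the mask are zeroed. Cropping a
#' cropped volume with its own tight mask is a no-op.
#'
#' @param volume a \linkS4class{PETVolume}.
#' @param mask a \linkS4class{BrainMask} of the same shape.
#' @return A \linkS4class{PETVolume}.
#' @export
cropToMask <- function(volume, mask) {
  .checkSameShape(volume, mask)
  bb <- .maskBoundingBox(mask@data)
  d <- volume@data
  d[!mask@data] <- 0
  sub <- d[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3], drop = FALSE]
  PETVolume(array(sub, bb$hi - bb$lo + 1L), volume@spacing)
}
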