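#' @include AllClasses.R
NULL

#' Morphological ball dilation of a binary mask
#'
#' Dilates with a discrete ball of the given physical radius: the per-axis
#' voxel radius is \code{round(radius / spacing)}, and an offset belongs to
#' the structuring element iff its ellipsoid-normalized distance is <= 1.
#' A 2 mm radius at 2 mm spacing therefore uses the 7-voxel 6-connected
#' unit ball. Radius 0 is the identity.
#'
#' @param mask a \linkS4class{BrainMask}.
#' @param radiusMM physical dilation radius in mm (>= 0).
#' @return the dilated \linkS4class{BrainMask} (always a superset).
#' @export
dilateMask <- function(mask, radiusMM) {
  if (radiusMM < 0) .err("error_badRadius", "dilation radius must be >= 0")
  r <- as.integer(round(radiusMM / mask@spacing))
  if (all(r == 0L)) return(mask)
  offs <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  rr <- pmax(r, 1L)
  keep <- (offs$dx / rr[1])^2 + (offs$dy / rr[2])^2 + (offs$dz / rr[3])^2 <= 1 + 1e-9
  offs <- offs[keep, , drop = FALSE]
  out <- array(FALSE, dim(mask@data))
  for (i in seq_len(nrow(offs))) {
    sh <- mask@data
    for (ax in 1:3) {
      o <- offs[i, ax]
      if (o != 0L) sh <- .shiftArray(sh, o, ax, fill = FALSE)
    }
    out <- out | sh
  }
  BrainMask(out, mask@spacing)
}

#' Voxel-intensity feature vector (comparator method)
#'
#' Collects the intensities of all mask voxels in deterministic x-fastest
#' order and standardizes them per image to zero mean and unit variance
#' (population variance), so the features are invariant to positive affine
#' intensity rescaling.
#'
#' @param volume a \linkS4class{PETVolume}.
#' @param mask a \linkS4class{BrainMask} of the same shape (typically the
#'   brain mask dilated by 2 mm).
#' @return numeric vector of length \code{sum(maskData(mask))}, named
#'   \code{vox_<ix>_<iy>_<iz>}.
#' @export
extractIntensityFeatures <- function(volume, mask) {
  .checkSameShape(volume, mask)
  x <- volume@data[mask@data]          # R arrays are x-fastest natively
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2))
  if (sdev == 0) {
    .err("error_zeroVariance", "image is constant within the mask")
  }
  feat <- (x - mu) / sdev
  idx <- which(mask@data, arr.ind = TRUE)
  names(feat) <- paste0("vox_", idx[, 1], "_", idx[, 2], "_", idx[, 3])
  feat
}
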