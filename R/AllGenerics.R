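#' @include AllClasses.R
NULL

#' Accessors for image containers
#'
#' \code{volData} returns the raw 3-D array, \code{voxelSpacing} the per-axis
#' voxel size in mm, \code{maskData} the logical array of a mask.
#'
#' @param x a \linkS4class{PETVolume} or \linkS4class{BrainMask}.
#' @return array or numeric(3).
#' @rdname accessors
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname accessors
#' @export
setGeneric("maskData", function(x) standardGeneric("maskData"))

#' Polyhedron accessors
#'
#' \code{faceCenters} returns the n_bins x 3 matrix of unit face-center
#' directions, \code{projectionThreshold} the scalar threshold t, and
#' \code{nBins} the number of histogram bins.
#'
#' @param x an \linkS4class{OrientationPolyhedron}.
#' @rdname polyAccessors
#' @export
setGeneric("faceCenters", function(x) standardGeneric("faceCenters"))

#' @rdname polyAccessors
#' @export
setGeneric("projectionThreshold", function(x) standardGeneric("projectionThreshold"))

#' @rdname polyAccessors
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @rdname accessors
#' @export
setMethod("volData", "PETVolume", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("voxelSpacing", "PETVolume", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("voxelSpacing", "BrainMask", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("maskData", "BrainMask", function(x) x@data)

#' @rdname polyAccessors
#' @export
setMethod("faceCenters", "OrientationPolyhedron", function(x) x@P)

#' @rdname polyAccessors
#' @export
setMethod("projectionThreshold", "OrientationPolyhedron", function(x) x@threshold)

#' @rdname polyAccessors
#' @export
setMethod("nBins", "OrientationPolyhedron", function(x) nrow(x@P))

setMethod("show", "PETVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("PETVolume %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(format(object@spacing), collapse = " x ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "BrainMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("BrainMask %d x %d x %d voxels, %d in mask\n",
              d[1], d[2], d[3], sum(object@data)))
})

setMethod("show", "OrientationPolyhedron", function(object) {
  cat(sprintf("OrientationPolyhedron: %s, %s-orientation, %d bins, t = %.6f\n",
              object@kind, if (object@half) "half" else "full",
              nrow(object@P), object@threshold))
})

setMethod("show", "HOGParams", function(object) {
  cat(sprintf("HOGParams: k = %d, S = %d, %s, %s-orientation\n",
              object@k, object@S, object@kind,
              if (object@half) "half" else "full"))
})

setMethod("show", "SUVRReport", function(object) {
  cat(sprintf("SUVRReport (%s): composite = %.4f, threshold = %.4f -> %s\n",
              object@tracer, object@composite, object@threshold,
              if (object@positive) "amyloid POSITIVE" else "amyloid negative"))
  for (nm in names(object@regional)) {
    cat(sprintf("  %-20s %.4f\n", nm, object@regional[[nm]]))
  }
})

setMethod("show", "ClassificationReport", function(object) {
  cat(sprintf(paste0("ClassificationReport: n = %d, accuracy = %.3f, ",
                     "sensitivity = %.3f, specificity = %.3f, AUC = %.3f\n"),
              nrow(object@subjects), object@accuracy, object@sensitivity,
              object@specificity, object@auc))
})

setMethod("show", "PhantomBundle", function(object) {
  d <- dim(object@volume@data)
  cat(sprintf("PhantomBundle: %s, %d x %d x %d voxels, true composite SUVR %.3f\n",
              object@label, d[1], d[2], d[3], object@trueSUVR))
})
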