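#' @include utils.R
NULL

#' PETVolume: a 3-D scalar tracer-uptake image
#'
#' Container for a skull-stripped, spatially normalized PET volume: a 3-D
#' numeric array of tracer uptake (arbitrary units) plus the per-axis voxel
#' size in mm. Voxel indices are 1-based with axes ordered (x, y, z).
#'
#' @slot data 3-D numeric array; all values finite.
#' @slot spacing numeric(3), voxel size in mm per axis, all > 0.
#' @export
setClass("PETVolume", slots = c(data = "array", spacing = "numeric"))

setValidity("PETVolume", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a 3-D array")
  if (any(d < 1L)) return("all three dimensions must be >= 1")
  if (length(object@spacing) != 3L) return("spacing must have length 3")
  if (any(!is.finite(object@spacing)) || any(object@spacing <= 0)) {
    return("spacing components must be finite and > 0")
  }
  if (any(!is.finite(object@data))) return("volume contains non-finite voxels")
  TRUE
})

#' BrainMask: a binary voxel mask
#'
#' @slot data 3-D logical array with at least one TRUE voxel.
#' @slot spacing numeric(3), voxel size in mm per axis.
#' @export
setClass("BrainMask", slots = c(data = "array", spacing = "numeric"))

setValidity("BrainMask", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("mask data must be a 3-D array")
  if (!is.logical(object@data)) return("mask data must be logical")
  if (!any(object@data)) return("mask must contain at least one TRUE voxel")
  if (length(object@spacing) != 3L || any(object@spacing <= 0)) {
    return("spacing must be numeric(3) > 0")
  }
  TRUE
})

#' Cuboid: an axis-aligned box of voxels
#'
#' Origin is the 1-based (x, y, z) index of the lowest corner; size is the
#' voxel count per axis (inclusive extent origin .. origin + size - 1).
#'
#' @slot origin integer(3), 1-based lowest corner.
#' @slot size integer(3), voxel counts, all >= 1.
#' @export
setClass("Cuboid", slots = c(origin = "integer", size = "integer"))

setValidity("Cuboid", function(object) {
  if (length(object@origin) != 3L || length(object@size) != 3L) {
    return("origin and size must have length 3")
  }
  if (any(object@origin < 1L)) return("origin indices must be >= 1")
  if (any(object@size < 1L)) return("size components must be >= 1")
  TRUE
})

#' GradientField: per-voxel 3-D image gradient
#'
#' Finite-difference gradient of a volume, one array per component, in
#' intensity units per voxel (spacing is not folded in).
#'
#' @slot gx,gy,gz 3-D numeric arrays of identical shape.
#' @export
setClass("GradientField", slots = c(gx = "array", gy = "array", gz = "array"))

setValidity("GradientField", function(object) {
  d <- dim(object@gx)
  if (!identical(d, dim(object@gy)) || !identical(d, dim(object@gz))) {
    return("gx, gy, gz must share one shape")
  }
  if (any(!is.finite(object@gx)) || any(!is.finite(object@gy)) ||
      any(!is.finite(object@gz))) {
    return("gradient field must be finite everywhere")
  }
  TRUE
})

#' IntegralGradientVolume: cumulative sums of a gradient field
#'
#' Entry (x, y, z) of each component holds the sum of that gradient
#' component over all voxels (x' <= x, y' <= y, z' <= z), enabling O(1)
#' cuboid sums by 8-corner inclusion-exclusion.
#'
#' @slot ix,iy,iz 3-D numeric arrays (double precision accumulators).
#' @export
setClass("IntegralGradientVolume",
         slots = c(ix = "array", iy = "array", iz = "array"))

#' OrientationPolyhedron: Platonic-solid orientation bins
#'
#' Face-center unit directions of a regular polyhedron used to quantize 3-D
#' gradient orientations. In half-orientation mode one face of each
#' antipodal pair is retained and projections are folded by absolute value,
#' making votes invariant to gradient sign.
#'
#' @slot kind one of "tetrahedron", "hexahedron", "octahedron",
#'   "dodecahedron", "icosahedron".
#' @slot P n_bins x 3 matrix of unit face-center directions.
#' @slot half logical, half-orientation flag.
#' @slot threshold projection threshold t (cosine of the adjacent-face
#'   angle of the full face set).
#' @export
setClass("OrientationPolyhedron",
         slots = c(kind = "character", P = "matrix", half = "logical",
                   threshold = "numeric"))

setValidity("OrientationPolyhedron", function(object) {
  faces <- c(tetrahedron = 4L, hexahedron = 6L, octahedron = 8L,
             dodecahedron = 12L, icosahedron = 20L)
  if (!object@kind %in% names(faces)) return("unknown polyhedron kind")
  nFull <- faces[[object@kind]]
  nExp <- if (object@half) nFull %/% 2L else nFull
  if (nrow(object@P) != nExp) {
    return(sprintf("expected %d face directions, got %d", nExp, nrow(object@P)))
  }
  if (ncol(object@P) != 3L) return("P must have 3 columns")
  nrm <- sqrt(rowSums(object@P^2))
  if (any(abs(nrm - 1) > 1e-12)) return("face directions must be unit vectors")
  if (!(object@threshold > 0 && object@threshold < 1)) {
    return("threshold must lie in (0, 1)")
  }
  TRUE
})

#' HOGParams: 3-D HOG descriptor parameters
#'
#' @slot k cell edge length in voxels (>= 1).
#' @slot S sub-blocks per axis within each cell; k must be divisible by S.
#' @slot kind polyhedron kind for orientation quantization.
#' @slot half logical, half-orientation histograms.
#' @slot normalizeCells logical, optional per-cell L2 normalization
#'   (off by default; the descriptor's native weighting is the gradient
#'   magnitude itself).
#' @slot concatSubblocks logical, alternative layout that concatenates the
#'   S^3 sub-block votes per cell instead of summing them (off by default).
#' @export
setClass("HOGParams",
         slots = c(k = "integer", S = "integer", kind = "character",
                   half = "logical", normalizeCells = "logical",
                   concatSubblocks = "logical"))

setValidity("HOGParams", function(object) {
  if (object@k < 1L) return("k must be >= 1")
  if (!object@S %in% c(1L, 2L, 4L)) return("S must be 1, 2 or 4")
  if (object@k %% object@S != 0L) return("k must be divisible by S")
  if (!object@kind %in% c("dodecahedron", "icosahedron")) {
    return("kind must be 'dodecahedron' or 'icosahedron'")
  }
  TRUE
})

#' RegionSet: SUVR target and reference regions
#'
#' @slot targets named list of \linkS4class{BrainMask} target regions.
#' @slot reference \linkS4class{BrainMask} reference region (e.g. whole
#'   cerebellum), disjoint from every target.
#' @slot tracer tracer name the thresholds refer to.
#' @export
setClass("RegionSet",
         slots = c(targets = "list", reference = "BrainMask",
                   tracer = "character"))

setValidity("RegionSet", function(object) {
  if (length(object@targets) < 1L) return("at least one target region required")
  if (is.null(names(object@targets)) || any(names(object@targets) == "")) {
    return("target regions must be named")
  }
  refd <- dim(object@reference@data)
  for (nm in names(object@targets)) {
    m <- object@targets[[nm]]
    if (!is(m, "BrainMask")) return("targets must be BrainMask objects")
    if (!identical(dim(m@data), refd)) return("region shapes must agree")
    if (any(m@data & object@reference@data)) {
      return(sprintf("target '%s' overlaps the reference region", nm))
    }
  }
  TRUE
})

#' SUVRReport: regional and composite uptake ratios with a status call
#'
#' @slot regional named numeric, per-target SUVR.
#' @slot composite unweighted mean of the regional SUVRs.
#' @slot threshold positivity threshold applied.
#' @slot positive logical, TRUE iff composite strictly exceeds threshold.
#' @slot tracer tracer name.
#' @export
setClass("SUVRReport",
         slots = c(regional = "numeric", composite = "numeric",
                   threshold = "numeric", positive = "logical",
                   tracer = "character"))

setValidity("SUVRReport", function(object) {
  if (abs(object@composite - mean(object@regional)) > 1e-12 * max(1, abs(object@composite))) {
    return("composite must equal the mean of regional SUVRs")
  }
  if (!identical(object@positive, object@composite > object@threshold)) {
    return("status must be composite > threshold (strict)")
  }
  TRUE
})

#' PhantomSpec: parameters of the synthetic PET phantom
#'
#' Defaults describe a 2 mm isotropic, 80 x 96 x 80 voxel brain-like
#' phantom whose amyloid-negative form keeps grey/white-matter contrast and
#' whose positive form loses it in six cortical target sectors.
#'
#' @slot shape integer(3) grid extents (voxels).
#' @slot spacing numeric(3) voxel size in mm.
#' @slot whiteIntensity white-matter core intensity.
#' @slot greyIntensity grey-matter shell intensity (negative case: < white).
#' @slot referenceIntensity cerebellum-like reference-region intensity.
#' @slot uptakeFactor multiplier applied to target-sector grey matter
#'   (> 1 makes the phantom amyloid positive).
#' @slot psfFWHM Gaussian point-spread FWHM in mm.
#' @slot biasAmplitude multiplicative low-frequency bias amplitude in [0, 0.5].
#' @slot noiseSD additive Gaussian noise standard deviation.
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomSpec",
         slots = c(shape = "integer", spacing = "numeric",
                   whiteIntensity = "numeric", greyIntensity = "numeric",
                   referenceIntensity = "numeric", uptakeFactor = "numeric",
                   psfFWHM = "numeric", biasAmplitude = "numeric",
                   noiseSD = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (length(object@shape) != 3L || any(object@shape < 16L)) {
    return("shape must be integer(3), each extent >= 16")
  }
  if (any(object@spacing <= 0)) return("spacing must be > 0")
  if (object@whiteIntensity <= 0 || object@greyIntensity <= 0 ||
      object@referenceIntensity <= 0) {
    return("tissue intensities must be > 0")
  }
  if (object@uptakeFactor < 1) return("uptakeFactor must be >= 1")
  if (object@psfFWHM < 0) return("psfFWHM must be >= 0")
  if (object@biasAmplitude < 0 || object@biasAmplitude > 0.5) {
    return("biasAmplitude must lie in [0, 0.5]")
  }
  if (object@noiseSD < 0) return("noiseSD must be >= 0")
  TRUE
})

#' PhantomBundle: one synthetic subject with ground truth
#'
#' @slot volume the simulated \linkS4class{PETVolume}.
#' @slot brainMask brain \linkS4class{BrainMask}.
#' @slot regions \linkS4class{RegionSet} of six target sectors plus an
#'   inferior reference blob, matched to this phantom's geometry.
#' @slot label "positive" or "negative" ground truth.
#' @slot trueSUVR composite SUVR of the noiseless, unblurred construction.
#' @slot spec the \linkS4class{PhantomSpec} used.
#' @slot metadata list (RNG algorithm, jitter draws, ...).
#' @export
setClass("PhantomBundle",
         slots = c(volume = "PETVolume", brainMask = "BrainMask",
                   regions = "RegionSet", label = "character",
                   trueSUVR = "numeric", spec = "PhantomSpec",
                   metadata = "list"))

#' TrainedSVM: a fitted RBF-kernel support vector machine
#'
#' Wraps the underlying fit together with its hyperparameters and the label
#' level order, so decision values can be oriented consistently (positive
#' decision value = predicted amyloid positive).
#'
#' @slot fit the underlying e1071 svm object.
#' @slot cost slackness parameter C.
#' @slot gamma RBF kernel width.
#' @export
setClass("TrainedSVM",
         slots = c(fit = "ANY", cost = "numeric", gamma = "numeric"))

#' ClassificationReport: leave-one-out (or test-set) evaluation summary
#'
#' @slot subjects data.frame with one row per subject: id, label, predicted,
#'   distance (signed decision value, positive = predicted positive) and
#'   normDistance (distance / max |distance| over the cohort).
#' @slot accuracy,sensitivity,specificity scalar rates; sensitivity treats
#'   amyloid positive as the "disease" class.
#' @slot auc area under the ROC curve of the signed distances.
#' @slot roc data.frame of (fpr, tpr) points.
#' @slot hyperParams list(cost, gamma) used.
#' @export
setClass("ClassificationReport",
         slots = c(subjects = "data.frame", accuracy = "numeric",
                   sensitivity = "numeric", specificity = "numeric",
                   auc = "numeric", roc = "data.frame",
                   hyperParams = "list"))
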