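#' @include AllClasses.R
NULL

#' Construct a PhantomSpec
#'
#' Defaults emulate a 2 mm isotropic, spatially normalized amyloid PET
#' scan: a white-matter ellipsoidal core (intensity 2.0) inside a
#' grey-matter shell (1.2), a cerebellum-like inferior reference blob at
#' grey-matter intensity, an 8 mm Gaussian point-spread function, a +-10%
#' low-frequency multiplicative bias field and additive Gaussian noise
#' (sd 0.1). An amyloid-negative phantom keeps the grey/white contrast; a
#' positive one multiplies the six target sectors' grey matter by the
#' uptake factor (default 1.5), reproducing the local loss of grey/white
#' contrast that distinguishes positive scans.
#'
#' @param shape integer(3) grid extents (default 80 x 96 x 80).
#' @param spacing numeric(3) voxel size in mm (default 2).
#' @param whiteIntensity white-matter intensity (default 2).
#' @param greyIntensity grey-matter intensity (default 1.2).
#' @param referenceIntensity reference-region intensity (default =
#'   greyIntensity, so a noiseless phantom's composite SUVR equals the
#'   uptake factor exactly).
#' @param uptakeFactor target-sector multiplier; 1 = negative, > 1 =
#'   positive (default 1.5).
#' @param psfFWHM Gaussian PSF full width at half maximum in mm (default 8).
#' @param biasAmplitude multiplicative bias amplitude (default 0.1).
#' @param noiseSD additive Gaussian noise sd (default 0.1).
#' @param seed integer RNG seed (default 0).
#' @return A \linkS4class{PhantomSpec}.
#' @export
PhantomSpec <- function(shape = c(80L, 96L, 80L), spacing = c(2, 2, 2),
                        whiteIntensity = 2, greyIntensity = 1.2,
                        referenceIntensity = greyIntensity,
                        uptakeFactor = 1.5, psfFWHM = 8,
                        biasAmplitude = 0.1, noiseSD = 0.1, seed = 0L) {
  new("PhantomSpec", shape = as.integer(shape), spacing = as.double(spacing),
      whiteIntensity = whiteIntensity, greyIntensity = greyIntensity,
      referenceIntensity = referenceIntensity, uptakeFactor = uptakeFactor,
      psfFWHM = psfFWHM, biasAmplitude = biasAmplitude, noiseSD = noiseSD,
      seed = as.integer(seed))
}

# idealized brain geometry, all lengths as fractions of the grid so the
# phantom scales with resolution. axisJitter shifts the cerebrum semi-axes
# (in voxels).
.phantomGeometry <- function(dims, axisJitter = c(0, 0, 0)) {
  g <- .coordGrids(dims)
  cx <- (dims[1] + 1) / 2
  cy <- (dims[2] + 1) / 2
  czCer <- 0.62 * dims[3]
  semi <- c(0.40 * dims[1], 0.42 * dims[2], 0.30 * dims[3]) + axisJitter
  ell <- function(s) ((g$x - cx) / s[1])^2 + ((g$y - cy) / s[2])^2 +
    ((g$z - czCer) / s[3])^2
  cerebrum <- ell(semi) <= 1
  wmCore <- ell(semi * 0.6) <= 1
  gmShell <- cerebrum & !wmCore
  # cerebellum-like reference blob, inferior and posterior, disjoint from
  # the cerebrum
  refC <- c(0.5 * dims[1], 0.40 * dims[2], 0.13 * dims[3])
  refR <- 0.10 * dims[3]
  reference <- ((g$x - refC[1])^2 + (g$y - refC[2])^2 +
                  (g$z - refC[3])^2) <= refR^2
  reference <- reference & !cerebrum
  # six 60-degree azimuthal sectors of the grey-matter shell
  theta <- atan2(g$y - cy, g$x - cx)
  sector <- pmin(floor((theta + pi) / (pi / 3)), 5)
  sectorNames <- c("frontal", "parietal", "anterior_cingulate",
                   "posterior_cingulate", "precuneus", "temporal")
  targets <- lapply(0:5, function(s) gmShell & sector == s)
  names(targets) <- sectorNames
  list(brain = cerebrum | reference, wmCore = wmCore, gmShell = gmShell,
       reference = reference, targets = targets)
}

.fwhmToSigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

.gaussianBlur <- function(a, sigmaVox) {
  if (sigmaVox <= 0) return(a)
  r <- max(1L, as.integer(ceiling(3 * sigmaVox)))
  kern <- stats::dnorm(seq(-r, r), sd = sigmaVox)
  kern <- kern / sum(kern)
  for (ax in 1:3) a <- .convAxis(a, kern, ax)
  a
}

#' Generate one synthetic PET phantom
#'
#' Builds the noiseless tissue model (white-matter core, grey-matter shell,
#' reference blob; target sectors scaled by the uptake factor), records its
#' exact composite SUVR, then applies in order: Gaussian PSF blur, a
#' smooth multiplicative bias field and additive Gaussian noise. All
#' randomness is drawn from the spec's seed, and the random draws do not
#' depend on the uptake factor, so phantoms generated from specs differing
#' only in \code{uptakeFactor} share identical bias and noise (paired
#' contrast experiments).
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param axisJitter numeric(3) perturbation of the cerebrum semi-axes in
#'   voxels (used by \code{\link{generateCohort}}).
#' @param intensityScale numeric(3) multipliers for (white, grey,
#'   reference) intensities (cohort jitter).
#' @return A \linkS4class{PhantomBundle}.
#' @export
generatePhantom <- function(spec, axisJitter = c(0, 0, 0),
                            intensityScale = c(1, 1, 1)) {
  validObject(spec)
  rng <- .seededRNG(spec@seed)
  dims <- spec@shape
  geom <- .phantomGeometry(dims, axisJitter)
  wI <- spec@whiteIntensity * intensityScale[1]
  gI <- spec@greyIntensity * intensityScale[2]
  rI <- spec@referenceIntensity * intensityScale[3]
  vol <- array(0, dims)
  vol[geom$wmCore] <- wI
  vol[geom$gmShell] <- gI
  vol[geom$reference] <- rI
  for (m in geom$targets) vol[m] <- gI * spec@uptakeFactor
  # exact composite SUVR of the noiseless, unblurred construction
  refMean <- mean(vol[geom$reference])
  trueSUVR <- mean(vapply(geom$targets, function(m) mean(vol[m]) / refMean,
                          numeric(1)))
  # PSF blur (isotropic spacing assumed; sigma in voxels per axis)
  sigmaVox <- .fwhmToSigma(spec@psfFWHM) / spec@spacing[1]
  vol <- .gaussianBlur(vol, sigmaVox)
  # low-frequency multiplicative bias field: random oblique cosine. The
  # phase/direction draws happen regardless of amplitude so seeds stay
  # aligned across amplitude settings.
  ph <- rng$runif(1, 0, 2 * pi)
  dir <- rng$runif(3, 0.5, 1.5)
  g <- .coordGrids(dims)
  field <- cos(pi * (dir[1] * g$x / dims[1] + dir[2] * g$y / dims[2] +
                       dir[3] * g$z / dims[3]) + ph)
  vol <- vol * (1 + spec@biasAmplitude * field)
  # additive Gaussian noise, drawn regardless of sd
  noise <- rng$rnorm(prod(dims))
  vol <- vol + spec@noiseSD * array(noise, dims)
  regions <- RegionSet(
    targets = lapply(geom$targets, BrainMask, spacing = spec@spacing),
    reference = BrainMask(geom$reference, spacing = spec@spacing),
    tracer = "florbetapir")
  new("PhantomBundle",
      volume = PETVolume(vol, spec@spacing),
      brainMask = BrainMask(geom$brain, spacing = spec@spacing),
      regions = regions,
      label = if (spec@uptakeFactor > 1) "positive" else "negative",
      trueSUVR = trueSUVR, spec = spec,
      metadata = list(rng = "Mersenne-Twister", axisJitter = axisJitter,
                      intensityScale = intensityScale))
}

#' Generate a labelled phantom cohort
#'
#' Draws per-subject jitter (+-10% on the three tissue intensities, +-1
#' voxel on the cerebrum semi-axes) from a single seeded stream, then
#' generates \code{nPos} positive and \code{nNeg} negative phantoms with
#' per-subject seeds derived from \code{seed}.
#'
#' @param nPos,nNeg numbers of amyloid-positive / negative subjects.
#' @param spec base \linkS4class{PhantomSpec}; its \code{uptakeFactor} is
#'   used for the positives, 1 for the negatives.
#' @param seed cohort seed.
#' @return list with \code{bundles} (list of \linkS4class{PhantomBundle})
#'   and \code{labels} (data.frame of subject, label, trueSUVR).
#' @export
generateCohort <- function(nPos, nNeg, spec = PhantomSpec(), seed = 0L) {
  n <- nPos + nNeg
  rng <- .seededRNG(seed)
  bundles <- vector("list", n)
  labels <- character(n)
  trueSUVR <- numeric(n)
  for (i in seq_len(n)) {
    positive <- i <= nPos
    iScale <- 1 + rng$runif(3, -0.1, 0.1)
    aJit <- rng$runif(3, -1, 1)
    si <- PhantomSpec(shape = spec@shape, spacing = spec@spacing,
                      whiteIntensity = spec@whiteIntensity,
                      greyIntensity = spec@greyIntensity,
                      referenceIntensity = spec@referenceIntensity,
                      uptakeFactor = if (positive) spec@uptakeFactor else 1,
                      psfFWHM = spec@psfFWHM,
                      biasAmplitude = spec@biasAmplitude,
                      noiseSD = spec@noiseSD,
                      seed = spec@seed + seed + 1000L * i)
    bundles[[i]] <- generatePhantom(si, axisJitter = aJit,
                                    intensityScale = iScale)
    labels[i] <- bundles[[i]]@label
    trueSUVR[i] <- bundles[[i]]@trueSUVR
  }
  list(bundles = bundles,
       labels = data.frame(subject = paste0("phantom_", seq_len(n)),
                           label = labels, trueSUVR = trueSUVR,
                           stringsAsFactors = FALSE))
}

#' Write a cohort to disk (NIfTI volumes + label map + labels CSV + spec)
#'
#' @param cohort result of \code{\link{generateCohort}}.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(cohort$bundles)) {
    b <- cohort$bundles[[i]]
    writeVolume(b@volume, file.path(dir, sprintf("phantom_%03d.nii.gz", i)))
  }
  b1 <- cohort$bundles[[1]]
  lab <- array(0, dim(b1@volume@data))
  nm <- names(b1@regions@targets)
  for (j in seq_along(nm)) lab[b1@regions@targets[[j]]@data] <- j
  lab[b1@regions@reference@data] <- length(nm) + 1L
  img <- RNifti::asNifti(lab)
  RNifti::pixdim(img) <- b1@volume@spacing
  RNifti::writeNifti(img, file.path(dir, "regions.nii.gz"))
  regionMap <- c(stats::setNames(as.list(seq_along(nm)), nm),
                 list(reference = length(nm) + 1L))
  jsonlite::write_json(
    list(labels = regionMap,
         roles = as.list(c(stats::setNames(rep("target", length(nm)), nm),
                           reference = "reference"))),
    file.path(dir, "regions.json"), auto_unbox = TRUE)
  utils::write.csv(cohort$labels, file.path(dir, "labels.csv"),
                   row.names = FALSE)
  s <- cohort$bundles[[1]]@spec
  jsonlite::write_json(
    list(shape = s@shape, spacing = s@spacing, whiteIntensity = s@whiteIntensity,
         greyIntensity = s@greyIntensity, referenceIntensity = s@referenceIntensity,
         uptakeFactor = s@uptakeFactor, psfFWHM = s@psfFWHM,
         biasAmplitude = s@biasAmplitude, noiseSD = s@noiseSD,
         rng = "Mersenne-Twister"),
    file.path(dir, "spec.json"), auto_unbox = TRUE)
  invisible(dir)
}
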