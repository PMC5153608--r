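#' @include AllClasses.R
NULL

# affine coefficients of the two published cross-scale regressions
.JAGUST_TO_JOSHI <- c(slope = 0.67, intercept = 0.15)
.JOSHI_TO_SPAP <- c(slope = 0.9782, intercept = 0.04264)

#' Tracer-specific amyloid-positivity thresholds on the sPAP scale
#'
#' florbetapir 1.12, florbetaben 1.36, and PiB 1.15 (the PiB value is the
#' published cerebellar-grey threshold 1.465 converted through the two
#' cross-scale regressions; see \code{\link{jagustToSpap}}).
#'
#' @param tracer one of "florbetapir", "florbetaben", "pib".
#' @return scalar positivity threshold.
#' @export
suvrThreshold <- function(tracer = c("florbetapir", "florbetaben", "pib")) {
  tracer <- match.arg(tolower(tracer), c("florbetapir", "florbetaben", "pib"))
  c(florbetapir = 1.12, florbetaben = 1.36, pib = 1.15)[[tracer]]
}

#' Construct a RegionSet
#'
#' @param targets named list of \linkS4class{BrainMask} target regions.
#' @param reference \linkS4class{BrainMask} reference region, disjoint from
#'   every target.
#' @param tracer tracer name (default "florbetapir").
#' @return A \linkS4class{RegionSet}.
#' @export
RegionSet <- function(targets, reference, tracer = "florbetapir") {
  new("RegionSet", targets = targets, reference = reference, tracer = tracer)
}

#' Regional standardized uptake value ratio
#'
#' Mean tracer uptake over the target voxels divided by the mean over the
#' reference voxels.
#'
#' @param volume a \linkS4class{PETVolume}.
#' @param target,reference \linkS4class{BrainMask}s of the volume's shape.
#' @return scalar SUVR.
#' @export
regionalSUVR <- function(volume, target, reference) {
  .checkSameShape(volume, target)
  .checkSameShape(volume, reference)
  refMean <- mean(volume@data[reference@data])
  if (!is.finite(refMean) || refMean <= 0) {
    .err("error_badReference", "reference region mean must be > 0")
  }
  mean(volume@data[target@data]) / refMean
}

#' Composite SUVR with a positivity decision
#'
#' Computes each target region's SUVR against the shared reference,
#' averages them (unweighted by default) into the composite, and calls the
#' scan positive iff the composite strictly exceeds the threshold.
#'
#' @param volume a \linkS4class{PETVolume}.
#' @param regions a \linkS4class{RegionSet}.
#' @param threshold positivity threshold; defaults to the tracer's value
#'   from \code{\link{suvrThreshold}}.
#' @param volumeWeighted if TRUE, weight regional SUVRs by region voxel
#'   counts instead of the unweighted mean (off by default).
#' @return A \linkS4class{SUVRReport}.
#' @export
compositeSUVR <- function(volume, regions,
                          threshold = suvrThreshold(regions@tracer),
                          volumeWeighted = FALSE) {
  regional <- vapply(regions@targets, function(m) {
    regionalSUVR(volume, m, regions@reference)
  }, numeric(1))
  if (volumeWeighted) {
    w <- vapply(regions@targets, function(m) sum(m@data), numeric(1))
    composite <- sum(regional * w) / sum(w)
    # the report's composite slot is defined as the plain mean; keep the
    # weighted value alongside
    rep <- new("SUVRReport", regional = regional, composite = mean(regional),
               threshold = threshold, positive = mean(regional) > threshold,
               tracer = regions@tracer)
    attr(rep, "weightedComposite") <- composite
    return(rep)
  }
  composite <- mean(regional)
  new("SUVRReport", regional = regional, composite = composite,
      threshold = threshold, positive = composite > threshold,
      tracer = regions@tracer)
}

#' Convert amyloid-positivity thresholds across quantification scales
#'
#' \code{jagustToJoshi} and \code{joshiToSpap} evaluate the two published
#' affine regressions t_Joshi = 0.67 t_Jagust + 0.15 and
#' t_sPAP = 0.9782 t_Joshi + 0.04264. \code{jagustToSpap} composes them
#' exactly (slope 0.9782 * 0.67, intercept 0.9782 * 0.15 + 0.04264), rather
#' than using the rounded printed coefficients;
#' \code{jagustToSpapCoefficients} reports the composed slope/intercept
#' rounded to 4 decimals (0.6554 and 0.1894).
#'
#' @param t threshold on the source scale (> 0 for thresholds; the affine
#'   map itself is defined everywhere).
#' @return converted threshold (or, for the coefficient accessor, a named
#'   numeric of slope and intercept).
#' @export
jagustToJoshi <- function(t) {
  .JAGUST_TO_JOSHI[["slope"]] * t + .JAGUST_TO_JOSHI[["intercept"]]
}

#' @rdname jagustToJoshi
#' @export
joshiToSpap <- function(t) {
  .JOSHI_TO_SPAP[["slope"]] * t + .JOSHI_TO_SPAP[["intercept"]]
}

#' @rdname jagustToJoshi
#' @export
jagustToSpap <- function(t) {
  joshiToSpap(jagustToJoshi(t))
}

#' @rdname jagustToJoshi
#' @export
jagustToSpapCoefficients <- function() {
  slope <- .JOSHI_TO_SPAP[["slope"]] * .JAGUST_TO_JOSHI[["slope"]]
  intercept <- .JOSHI_TO_SPAP[["slope"]] * .JAGUST_TO_JOSHI[["intercept"]] +
    .JOSHI_TO_SPAP[["intercept"]]
  c(slope = round(slope, 4), intercept = round(intercept, 4))
}

#' Write an SUVR report as JSON and CSV
#'
#' @param report a \linkS4class{SUVRReport}.
#' @param path output JSON path; per-region rows go to \code{<path>.csv}.
#' @return invisibly, the path.
#' @export
writeSUVRReport <- function(report, path) {
  obj <- list(tracer = report@tracer, composite = report@composite,
              threshold = report@threshold,
              status = if (report@positive) "positive" else "negative",
              regional = as.list(report@regional))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  df <- data.frame(region = names(report@regional), suvr = unname(report@regional))
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}
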