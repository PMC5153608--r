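#' @include AllClasses.R
NULL

#' Read a RegionSet from a label image and a JSON name map
#'
#' The label image is an integer NIfTI in the volume's space; the JSON map
#' assigns each region name an integer label and a role ("target" or
#' "reference"), in the layout written by \code{\link{writeCohort}}:
#' \code{{"labels": {name: int, ...}, "roles": {name: "target"|"reference"}}}.
#' Exactly one region must have the reference role.
#'
#' @param labelPath path to the integer-label NIfTI image.
#' @param mapPath path to the JSON name map.
#' @param tracer tracer name recorded in the set (default "florbetapir").
#' @return A \linkS4class{RegionSet}.
#' @export
readRegionSet <- function(labelPath, mapPath, tracer = "florbetapir") {
  lab <- readVolume(labelPath, allowAnisotropic = TRUE)
  map <- jsonlite::read_json(mapPath, simplifyVector = TRUE)
  if (is.null(map$labels) || is.null(map$roles)) {
    .err("error_badRegionMap", "region map needs 'labels' and 'roles' entries")
  }
  roles <- unlist(map$roles)
  labels <- unlist(map$labels)
  refNames <- names(roles)[roles == "reference"]
  if (length(refNames) != 1L) {
    .err("error_badRegionMap", "exactly one region must have role 'reference'")
  }
  tgtNames <- names(roles)[roles == "target"]
  if (length(tgtNames) < 1L) {
    .err("error_badRegionMap", "at least one target region required")
  }
  maskFor <- function(nm) {
    m <- lab@data == labels[[nm]]
    if (!any(m)) {
      .err("error_emptyMask", sprintf("region '%s' has no voxels", nm))
    }
    BrainMask(m, lab@spacing)
  }
  RegionSet(targets = stats::setNames(lapply(tgtNames, maskFor), tgtNames),
            reference = maskFor(refNames), tracer = tracer)
}
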