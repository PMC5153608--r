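#' @include AllClasses.R
NULL

#' Construct HOG descriptor parameters
#'
#' Defaults are the optimum configuration found by grid search on amyloid
#' PET: cell size k = 16 voxels, S = 1 sub-block, icosahedron,
#' half-orientation histograms.
#'
#' @param k cell edge length in voxels.
#' @param S sub-blocks per axis (1, 2 or 4); k must be divisible by S.
#' @param kind "icosahedron" or "dodecahedron".
#' @param half logical, half-orientation histograms.
#' @param normalizeCells logical, optional per-cell L2 normalization
#'   (epsilon 1e-12), off by default.
#' @param concatSubblocks logical, concatenate the S^3 sub-block votes per
#'   cell instead of summing them, off by default.
#' @return A \linkS4class{HOGParams}.
#' @export
HOGParams <- function(k = 16L, S = 1L, kind = "icosahedron", half = TRUE,
                      normalizeCells = FALSE, concatSubblocks = FALSE) {
  new("HOGParams", k = as.integer(k), S = as.integer(S), kind = kind,
      half = isTRUE(half), normalizeCells = isTRUE(normalizeCells),
      concatSubblocks = isTRUE(concatSubblocks))
}

#' Partition a grid into a uniform lattice of cells
#'
#' Places floor(dim / k) cells of exactly k^3 voxels per axis, anchored at
#' the centered offset floor((dim mod k) / 2) so that discarded partial-cell
#' margins are symmetric. Cells are returned x-fastest.
#'
#' @param shape integer(3) voxel extents.
#' @param k cell edge length; every extent must be >= k.
#' @return list of \linkS4class{Cuboid} cells; attribute \code{"gridShape"}
#'   holds the cells-per-axis counts.
#' @export
partitionCells <- function(shape, k) {
  shape <- as.integer(shape)
  k <- as.integer(k)
  if (any(shape < k)) {
    .err("error_tooSmall",
         sprintf("extents [%s] smaller than cell size %d",
                 paste(shape, collapse = ","), k))
  }
  nCells <- shape %/% k
  offset <- (shape %% k) %/% 2L
  grid <- expand.grid(ix = seq_len(nCells[1]), iy = seq_len(nCells[2]),
                      iz = seq_len(nCells[3]))
  cells <- lapply(seq_len(nrow(grid)), function(i) {
    ci <- as.integer(grid[i, ])
    Cuboid(origin = offset + (ci - 1L) * k + 1L, size = c(k, k, k))
  })
  attr(cells, "gridShape") <- nCells
  attr(cells, "cellIndex") <- as.matrix(grid)
  cells
}

# sub-block low/high corner index matrices for a set of cells
.subBlockCorners <- function(cells, k, S) {
  s <- k %/% S
  sub <- expand.grid(sx = seq_len(S), sy = seq_len(S), sz = seq_len(S))
  nSub <- nrow(sub)
  lo <- matrix(0L, length(cells) * nSub, 3L)
  for (ci in seq_along(cells)) {
    o <- cells[[ci]]@origin
    rows <- (ci - 1L) * nSub + seq_len(nSub)
    lo[rows, 1] <- o[1] + (sub$sx - 1L) * s
    lo[rows, 2] <- o[2] + (sub$sy - 1L) * s
    lo[rows, 3] <- o[3] + (sub$sz - 1L) * s
  }
  list(lo = lo, hi = lo + s - 1L, nSub = nSub, blockVoxels = s^3)
}

#' Orientation histogram of one cell
#'
#' Splits the cell into S^3 sub-blocks of edge k/S, computes each
#' sub-block's mean gradient from the integral volume, quantizes it on the
#' polyhedron, and sums the S^3 votes.
#'
#' @param ivol an \linkS4class{IntegralGradientVolume}.
#' @param cell a \linkS4class{Cuboid} of edge k lying inside the grid.
#' @param params a \linkS4class{HOGParams}.
#' @param poly an \linkS4class{OrientationPolyhedron} consistent with
#'   \code{params}.
#' @return numeric histogram of length \code{nBins(poly)}.
#' @export
cellHistogram <- function(ivol, cell, params, poly) {
  .checkCuboidInside(cell, dim(ivol@ix))
  if (!all(cell@size == params@k)) {
    .err("error_badCuboid", "cell size must equal k^3")
  }
  pads <- list(.padIntegral(ivol@ix), .padIntegral(ivol@iy), .padIntegral(ivol@iz))
  sb <- .subBlockCorners(list(cell), params@k, params@S)
  G <- .cuboidSums(pads, sb$lo, sb$hi) / sb$blockVoxels
  votes <- quantizeGradient(G, poly)
  colSums(votes)
}

#' Extract the 3-D HOG feature vector of a volume
#'
#' Computes the gradient field and its integral volume once, accumulates
#' per-cell orientation histograms over the centered cell lattice, and
#' concatenates them x-fastest with bins contiguous per cell.
#'
#' @param volume a \linkS4class{PETVolume} with every extent >= k.
#' @param params a \linkS4class{HOGParams}.
#' @return named numeric feature vector of length n_cells x n_bins (columns
#'   \code{cell_<ix>_<iy>_<iz>_bin_<b>}, 1-based); attributes
#'   \code{"gridShape"}, \code{"nBins"} and \code{"fallbacks"}.
#' @export
extractDescriptor <- function(volume, params = HOGParams()) {
  poly <- makePolyhedron(params@kind, params@half)
  cells <- partitionCells(dim(volume@data), params@k)
  ivol <- buildIntegral(computeGradient(volume))
  pads <- list(.padIntegral(ivol@ix), .padIntegral(ivol@iy), .padIntegral(ivol@iz))
  sb <- .subBlockCorners(cells, params@k, params@S)
  G <- .cuboidSums(pads, sb$lo, sb$hi) / sb$blockVoxels
  votes <- quantizeGradient(G, poly)
  fallbacks <- attr(votes, "fallbacks")
  nb <- ncol(votes)
  if (params@concatSubblocks) {
    # alternative layout: per cell, the S^3 sub-block votes side by side
    feat <- as.numeric(t(votes))
    hist <- matrix(feat, nrow = length(cells), byrow = TRUE)
  } else {
    cellOf <- rep(seq_along(cells), each = sb$nSub)
    hist <- rowsum(votes, cellOf)
  }
  if (params@normalizeCells) {
    hist <- hist / (sqrt(rowSums(hist^2)) + 1e-12)
  }
  feat <- as.numeric(t(hist))
  ci <- attr(cells, "cellIndex")
  if (params@concatSubblocks) {
    binTag <- paste0("sub_", rep(seq_len(sb$nSub), each = nb),
                     "_bin_", rep(seq_len(nb), times = sb$nSub))
  } else {
    binTag <- paste0("bin_", seq_len(nb))
  }
  names(feat) <- paste0("cell_", rep(ci[, 1], each = ncol(hist)), "_",
                        rep(ci[, 2], each = ncol(hist)), "_",
                        rep(ci[, 3], each = ncol(hist)), "_",
                        rep(binTag, times = length(cells)))
  attr(feat, "gridShape") <- attr(cells, "gridShape")
  attr(feat, "nBins") <- nb
  attr(feat, "fallbacks") <- fallbacks
  feat
}

#' Enumerate the HOG parameter search grid
#'
#' The full descriptor grid: k in {4, 8, ..., 32}, S in {1, 2, 4}, kind in
#' {dodecahedron, icosahedron}, orientation in {full, half} - 96
#' combinations in deterministic order.
#'
#' @return list of \linkS4class{HOGParams}.
#' @export
enumerateParamGrid <- function() {
  grid <- expand.grid(k = seq(4L, 32L, by = 4L), S = c(1L, 2L, 4L),
                      kind = c("dodecahedron", "icosahedron"),
                      half = c(FALSE, TRUE), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    HOGParams(k = grid$k[i], S = grid$S[i], kind = grid$kind[i],
              half = grid$half[i])
  })
}

#' Write / read a feature matrix as CSV
#'
#' One row per subject, columns named by cell/bin identifier; a sidecar
#' JSON records the descriptor parameters and grid shape.
#'
#' @param features numeric matrix (subjects x features) with column names,
#'   or a single named feature vector.
#' @param path CSV output path.
#' @param params optional \linkS4class{HOGParams} recorded in the sidecar.
#' @param ids optional subject identifiers (row names).
#' @return invisibly, the path.
#' @export
writeFeatureMatrix <- function(features, path, params = NULL, ids = NULL) {
  if (is.null(dim(features))) features <- matrix(features, 1L,
                                                 dimnames = list(NULL, names(features)))
  df <- as.data.frame(features)
  df <- cbind(subject = if (is.null(ids)) seq_len(nrow(df)) else ids, df)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(params)) {
    side <- list(k = params@k, S = params@S, kind = params@kind,
                 half = params@half, normalizeCells = params@normalizeCells,
                 concatSubblocks = params@concatSubblocks)
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- df$subject
  m <- as.matrix(df[, setdiff(colnames(df), "subject"), drop = FALSE])
  rownames(m) <- ids
  m
}
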