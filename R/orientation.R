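#' @include AllClasses.R
NULL

# golden ratio
.PHI <- (1 + sqrt(5)) / 2

# full face-center direction sets (unnormalized), standard golden-ratio
# constructions; the icosahedron's face centers are the dodecahedron's
# vertices and vice versa (dual solids).
.faceDirections <- function(kind) {
  phi <- .PHI
  cyc <- function(v) rbind(v, v[c(3, 1, 2)], v[c(2, 3, 1)])
  signs2 <- as.matrix(expand.grid(s1 = c(-1, 1), s2 = c(-1, 1)))
  if (kind == "icosahedron") {
    # 20 faces = dodecahedron vertices: (+-1,+-1,+-1) and cyclic (0, +-1/phi, +-phi)
    cube <- as.matrix(expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1)))
    rest <- do.call(rbind, lapply(seq_len(nrow(signs2)), function(i) {
      cyc(c(0, signs2[i, 1] / phi, signs2[i, 2] * phi))
    }))
    P <- rbind(cube, rest)
  } else if (kind == "dodecahedron") {
    # 12 faces = icosahedron vertices: cyclic (0, +-1, +-phi)
    P <- do.call(rbind, lapply(seq_len(nrow(signs2)), function(i) {
      cyc(c(0, signs2[i, 1], signs2[i, 2] * phi))
    }))
  } else {
    .err("error_badKind",
         sprintf("unsupported polyhedron kind '%s' (use dodecahedron or icosahedron)",
                 kind))
  }
  dimnames(P) <- NULL
  P / sqrt(rowSums(P^2))
}

# deterministic ordering so descriptors are comparable across runs: sort
# rows lexicographically by (x, y, z)
.orderRows <- function(P) {
  P[order(round(P[, 1], 12), round(P[, 2], 12), round(P[, 3], 12)), , drop = FALSE]
}

#' Construct an orientation-quantization polyhedron
#'
#' Builds the unit face-center direction matrix of a regular polyhedron and
#' the projection threshold t. t is the maximum pairwise dot product among
#' distinct, non-antipodal faces of the full face set (the adjacent-face
#' cosine): with this choice a gradient aligned with a face center votes in
#' exactly one bin. In half-orientation mode one face of each antipodal pair
#' is retained and projections are later folded by absolute value; by
#' default the full-set threshold is inherited (\code{thresholdMode =
#' "full"}), with \code{"folded"} recomputing it on the retained set.
#'
#' @param kind "dodecahedron" (12 faces) or "icosahedron" (20 faces).
#' @param half logical; retain one face per antipodal pair.
#' @param thresholdMode "full" (default) or "folded".
#' @return An \linkS4class{OrientationPolyhedron}.
#' @export
makePolyhedron <- function(kind = c("icosahedron", "dodecahedron"),
                           half = TRUE, thresholdMode = c("full", "folded")) {
  kind <- match.arg(kind)
  thresholdMode <- match.arg(thresholdMode)
  Pfull <- .orderRows(.faceDirections(kind))
  dots <- Pfull %*% t(Pfull)
  nonAnti <- abs(dots + 1) > 1e-9 & abs(dots - 1) > 1e-9
  tFull <- max(dots[nonAnti])
  P <- Pfull
  if (half) {
    # keep the representative whose first nonzero coordinate is positive
    keep <- apply(Pfull, 1, function(p) {
      nz <- p[abs(p) > 1e-12]
      nz[1] > 0
    })
    P <- Pfull[keep, , drop = FALSE]
  }
  t <- tFull
  if (half && thresholdMode == "folded") {
    dh <- abs(P %*% t(P))
    t <- max(dh[abs(dh - 1) > 1e-9])
  }
  new("OrientationPolyhedron", kind = kind, P = P, half = half, threshold = t)
}

#' Quantize 3-D gradients into orientation-histogram votes
#'
#' Each gradient g is projected onto the face-center directions
#' (q_hat = P g / |g|; absolute values in half mode), the threshold t is
#' subtracted with negative entries clamped to zero, and the result is
#' rescaled so the vote's L2 norm equals |g| (magnitude-preserving
#' distribution over bins). A zero gradient contributes a zero vote. If the
#' thresholded projection vanishes for a nonzero gradient (numerically
#' possible only for t above the covering cosine) the full magnitude is
#' assigned to the best-aligned bin (lowest index on ties) and the event is
#' counted in the \code{"fallbacks"} attribute.
#'
#' @param g numeric(3) gradient, or an n x 3 matrix of gradients.
#' @param poly an \linkS4class{OrientationPolyhedron}.
#' @return For a single gradient, a numeric vote of length \code{nBins(poly)};
#'   for a matrix, an n x nBins matrix. Attribute \code{"fallbacks"} counts
#'   argmax fallbacks.
#' @export
quantizeGradient <- function(g, poly) {
  single <- is.null(dim(g))
  G <- if (single) matrix(as.double(g), 1L, 3L) else as.matrix(g)
  if (ncol(G) != 3L) .err("error_badGradient", "gradients must have 3 components")
  if (any(!is.finite(G))) .err("error_nonfinite", "non-finite gradient")
  nb <- nrow(poly@P)
  mag <- sqrt(rowSums(G^2))
  Q <- matrix(0, nrow(G), nb)
  nz <- mag > 0
  fallbacks <- 0L
  if (any(nz)) {
    U <- G[nz, , drop = FALSE] / mag[nz]
    qhat <- U %*% t(poly@P)
    if (poly@half) qhat <- abs(qhat)
    qp <- pmax(qhat - poly@threshold, 0)
    # numerical guard: exact adjacent-face projections equal t up to fp error
    qp[qp <= 1e-9] <- 0
    nrm <- sqrt(rowSums(qp^2))
    bad <- nrm == 0
    if (any(bad)) {
      fallbacks <- sum(bad)
      amax <- max.col(qhat[bad, , drop = FALSE], ties.method = "first")
      qp[cbind(which(bad), amax)] <- 1
      nrm[bad] <- 1
    }
    Q[nz, ] <- (mag[nz] / nrm) * qp
  }
  out <- if (single) Q[1L, ] else Q
  attr(out, "fallbacks") <- fallbacks
  out
}

#' Export polyhedron geometry as JSON
#'
#' Writes face-center coordinates and the projection threshold for
#' cross-implementation verification.
#'
#' @param poly an \linkS4class{OrientationPolyhedron}.
#' @param path output JSON path; if NULL the JSON string is returned.
#' @return the path (invisibly) or a JSON string.
#' @export
polyhedronToJSON <- function(poly, path = NULL) {
  obj <- list(kind = poly@kind, half = poly@half, threshold = poly@threshold,
              n_bins = nrow(poly@P), faces = unname(apply(poly@P, 1, as.numeric,
                                                          simplify = FALSE)))
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}
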