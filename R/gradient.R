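#' @include AllClasses.R
NULL

#' Construct a Cuboid
#'
#' @param origin integer(3), 1-based lowest-corner voxel index.
#' @param size integer(3), voxel counts per axis.
#' @return A \linkS4class{Cuboid}.
#' @export
Cuboid <- function(origin, size) {
  if (!.isWholeNumber(origin) || !.isWholeNumber(size)) {
    .err("error_badCuboid", "origin and size must be whole numbers")
  }
  new("Cuboid", origin = as.integer(round(origin)), size = as.integer(round(size)))
}

# one-axis finite differences: central in the interior, one-sided at faces
.axisDiff <- function(v, axis) {
  d <- dim(v)
  n <- d[axis]
  fwd <- .shiftArray(v, -1L, axis)   # v[i+1]
  bwd <- .shiftArray(v, +1L, axis)   # v[i-1]
  g <- (fwd - bwd) / 2
  idx <- list(1:d[1], 1:d[2], 1:d[3])
  lo <- idx; lo[[axis]] <- 1L
  lo2 <- idx; lo2[[axis]] <- 2L
  hi <- idx; hi[[axis]] <- n
  hi2 <- idx; hi2[[axis]] <- n - 1L
  g[lo[[1]], lo[[2]], lo[[3]]] <-
    v[lo2[[1]], lo2[[2]], lo2[[3]]] - v[lo[[1]], lo[[2]], lo[[3]]]
  g[hi[[1]], hi[[2]], hi[[3]]] <-
    v[hi[[1]], hi[[2]], hi[[3]]] - v[hi2[[1]], hi2[[2]], hi2[[3]]]
  g
}

#' Per-voxel 3-D gradient of a volume
#'
#' Central differences in the interior, one-sided differences at the
#' boundary faces. Units are intensity per voxel: the voxel spacing is not
#' folded in, because the descriptor only uses orientations and relative
#' magnitudes and isotropic input is enforced upstream.
#'
#' @param volume a \linkS4class{PETVolume} with every dimension >= 2.
#' @return A \linkS4class{GradientField}.
#' @export
computeGradient <- function(volume) {
  d <- dim(volume@data)
  if (any(d < 2L)) {
    .err("error_tooSmall", "every dimension must be >= 2 to differentiate")
  }
  new("GradientField",
      gx = .axisDiff(volume@data, 1L),
      gy = .axisDiff(volume@data, 2L),
      gz = .axisDiff(volume@data, 3L))
}

#' Integral volume of a gradient field
#'
#' Per component, entry (x, y, z) holds the cumulative sum of that gradient
#' component over all voxels (x' <= x, y' <= y, z' <= z). Accumulation is in
#' double precision.
#'
#' @param field a \linkS4class{GradientField}.
#' @return An \linkS4class{IntegralGradientVolume}.
#' @export
buildIntegral <- function(field) {
  cum3 <- function(a) .cumsumAxis(.cumsumAxis(.cumsumAxis(a, 1L), 2L), 3L)
  new("IntegralGradientVolume",
      ix = cum3(field@gx), iy = cum3(field@gy), iz = cum3(field@gz))
}

# zero-padded copy: pad[i+1, j+1, k+1] = I[i, j, k], pad[1,,] = 0 etc.
.padIntegral <- function(a) {
  d <- dim(a)
  p <- array(0, d + 1L)
  p[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- a
  p
}

.checkCuboidInside <- function(box, dims) {
  hi <- box@origin + box@size - 1L
  if (any(hi > dims)) {
    .err("error_outOfBounds",
         sprintf("cuboid [%s]+[%s] exceeds grid [%s]",
                 paste(box@origin, collapse = ","),
                 paste(box@size, collapse = ","),
                 paste(dims, collapse = ",")))
  }
}

# cuboid sums over padded integral arrays, vectorized over many cuboids.
# lo/hi are n x 3 matrices of 1-based inclusive corner indices.
.cuboidSums <- function(padList, lo, hi) {
  d <- dim(padList[[1]])
  lin <- function(x, y, z) x + d[1] * (y - 1L + d[2] * (z - 1L))
  a <- lo            # index into padded array of (low - 1)
  b <- hi + 1L       # index of high corner
  corner <- function(cx, cy, cz) {
    ix <- if (cx) b[, 1] else a[, 1]
    iy <- if (cy) b[, 2] else a[, 2]
    iz <- if (cz) b[, 3] else a[, 3]
    lin(ix, iy, iz)
  }
  out <- matrix(0, nrow(lo), length(padList))
  for (comp in seq_along(padList)) {
    p <- padList[[comp]]
    s <- p[corner(TRUE, TRUE, TRUE)] - p[corner(FALSE, TRUE, TRUE)] -
      p[corner(TRUE, FALSE, TRUE)] - p[corner(TRUE, TRUE, FALSE)] +
      p[corner(FALSE, FALSE, TRUE)] + p[corner(FALSE, TRUE, FALSE)] +
      p[corner(TRUE, FALSE, FALSE)] - p[corner(FALSE, FALSE, FALSE)]
    out[, comp] <- s
  }
  out
}

#' Mean gradient over a cuboid in O(1)
#'
#' Evaluates the 8-corner inclusion-exclusion sum of the integral gradient
#' volume over the cuboid and divides by its voxel count; equals the
#' arithmetic mean of the per-voxel gradients inside the cuboid.
#'
#' @param ivol an \linkS4class{IntegralGradientVolume}.
#' @param box a \linkS4class{Cuboid} lying inside the grid.
#' @return numeric(3): the mean gradient (gx, gy, gz).
#' @export
meanGradient <- function(ivol, box) {
  dims <- dim(ivol@ix)
  .checkCuboidInside(box, dims)
  pads <- list(.padIntegral(ivol@ix), .padIntegral(ivol@iy), .padIntegral(ivol@iz))
  lo <- matrix(box@origin, 1L, 3L)
  hi <- matrix(box@origin + box@size - 1L, 1L, 3L)
  as.numeric(.cuboidSums(pads, lo, hi)) / prod(box@size)
}
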