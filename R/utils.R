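# internal helpers shared across modules

#' @import methods
#' @importFrom stats rnorm runif predict
NULL

# classed error so callers can distinguish failure modes programmatically
.err <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(paste0("amyloidHOG_", class), "amyloidHOG_error")))
}

.isWholeNumber <- function(x, tol = 1e-8) {
  is.numeric(x) && all(is.finite(x)) && all(abs(x - round(x)) < tol)
}

# shift an array by `offset` voxels along `axis`, filling vacated voxels with `fill`
.shiftArray <- function(a, offset, axis, fill = 0) {
  d <- dim(a)
  if (offset == 0L) return(a)
  out <- array(fill, d)
  n <- d[axis]
  if (abs(offset) >= n) return(out)
  src <- if (offset > 0) 1:(n - offset) else (1 - offset):n
  dst <- if (offset > 0) (1 + offset):n else 1:(n + offset)
  idxSrc <- list(1:d[1], 1:d[2], 1:d[3])
  idxDst <- idxSrc
  idxSrc[[axis]] <- src
  idxDst[[axis]] <- dst
  out[idxDst[[1]], idxDst[[2]], idxDst[[3]]] <-
    a[idxSrc[[1]], idxSrc[[2]], idxSrc[[3]]]
  out
}

# in-place style cumulative sum along one axis (vectorized over the other two)
.cumsumAxis <- function(a, axis) {
  d <- dim(a)
  if (d[axis] < 2L) return(a)
  for (i in 2:d[axis]) {
    if (axis == 1L) a[i, , ] <- a[i, , ] + a[i - 1L, , ]
    else if (axis == 2L) a[, i, ] <- a[, i, ] + a[, i - 1L, ]
    else a[, , i] <- a[, , i] + a[, , i - 1L]
  }
  a
}

# separable convolution with a 1-D kernel along one axis, zero padding
.convAxis <- function(a, kern, axis) {
  r <- (length(kern) - 1L) %/% 2L
  out <- array(0, dim(a))
  for (o in seq(-r, r)) {
    out <- out + kern[o + r + 1L] * .shiftArray(a, o, axis)
  }
  out
}

# 3-D voxel-index coordinate grids (1-based), each an array of dim `dims`
.coordGrids <- function(dims) {
  list(
    x = array(seq_len(dims[1]), dims),
    y = array(rep(seq_len(dims[2]), each = dims[1]), dims),
    z = array(rep(seq_len(dims[3]), each = dims[1] * dims[2]), dims)
  )
}

# normalize assorted label encodings to factor(c("negative","positive"))
.asLabelFactor <- function(labels) {
  if (is.logical(labels)) {
    lab <- ifelse(labels, "positive", "negative")
  } else if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) .err("error_badLabels", "numeric labels must be 0/1")
    lab <- ifelse(labels == 1, "positive", "negative")
  } else {
    lab <- tolower(as.character(labels))
    if (!all(lab %in% c("positive", "negative"))) {
      .err("error_badLabels", "labels must be 'positive'/'negative' (or logical/0-1)")
    }
  }
  factor(lab, levels = c("negative", "positive"))
}
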