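# Independent brute-force oracles, deliberately written as plain loops /
# direct formulas so they share no code path with the package internals.

# per-voxel finite differences by explicit loops (central interior,
# one-sided at faces)
oracleGradient <- function(v) {
  d <- dim(v)
  gx <- gy <- gz <- array(0, d)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    gx[x, y, z] <- if (x == 1) v[2, y, z] - v[1, y, z]
      else if (x == d[1]) v[d[1], y, z] - v[d[1] - 1, y, z]
      else (v[x + 1, y, z] - v[x - 1, y, z]) / 2
    gy[x, y, z] <- if (y == 1) v[x, 2, z] - v[x, 1, z]
      else if (y == d[2]) v[x, d[2], z] - v[x, d[2] - 1, z]
      else (v[x, y + 1, z] - v[x, y - 1, z]) / 2
    gz[x, y, z] <- if (z == 1) v[x, y, 2] - v[x, y, 1]
      else if (z == d[3]) v[x, y, d[3]] - v[x, y, d[3] - 1]
      else (v[x, y, z + 1] - v[x, y, z - 1]) / 2
  }
  list(gx = gx, gy = gy, gz = gz)
}

# triple-loop cumulative sums
oracleIntegral <- function(a) {
  d <- dim(a)
  out <- array(0, d)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    out[x, y, z] <- sum(a[1:x, 1:y, 1:z])
  }
  out
}

# arithmetic mean of gradient components inside a cuboid, by subsetting
oracleMeanGradient <- function(g, origin, size) {
  xs <- origin[1]:(origin[1] + size[1] - 1)
  ys <- origin[2]:(origin[2] + size[2] - 1)
  zs <- origin[3]:(origin[3] + size[3] - 1)
  c(mean(g$gx[xs, ys, zs]), mean(g$gy[xs, ys, zs]), mean(g$gz[xs, ys, zs]))
}

# loop-over-faces re-implementation of the orientation vote
oracleQuantize <- function(g, P, t, half) {
  mag <- sqrt(sum(g^2))
  n <- nrow(P)
  if (mag == 0) return(numeric(n))
  qhat <- numeric(n)
  for (i in 1:n) {
    qhat[i] <- sum(P[i, ] * g) / mag
    if (half) qhat[i] <- abs(qhat[i])
  }
  qp <- numeric(n)
  for (i in 1:n) qp[i] <- max(qhat[i] - t, 0)
  qp[qp <= 1e-9] <- 0
  nrm <- sqrt(sum(qp^2))
  if (nrm == 0) {
    out <- numeric(n)
    out[which.max(qhat)] <- mag
    return(out)
  }
  mag * qp / nrm
}

# from-scratch descriptor: per-voxel gradients by index arithmetic (no
# integral volumes), then loops over cells and sub-blocks
oracleDescriptor <- function(v, k, S, P, t, half) {
  g <- list()
  d <- dim(v)
  idxDiff <- function(axis) {
    out <- array(0, d)
    for (i in 1:d[axis]) {
      lo <- max(i - 1, 1)
      hi <- min(i + 1, d[axis])
      sl <- function(j) switch(axis, v[j, , ], v[, j, ], v[, , j])
      val <- (sl(hi) - sl(lo)) / (hi - lo)
      if (axis == 1) out[i, , ] <- val
      else if (axis == 2) out[, i, ] <- val
      else out[, , i] <- val
    }
    out
  }
  g <- list(gx = idxDiff(1), gy = idxDiff(2), gz = idxDiff(3))
  nC <- d %/% k
  off <- (d %% k) %/% 2
  s <- k / S
  nb <- nrow(P)
  feat <- c()
  for (cz in 1:nC[3]) for (cy in 1:nC[2]) for (cx in 1:nC[1]) {
    o <- off + (c(cx, cy, cz) - 1) * k + 1
    h <- numeric(nb)
    for (bz in 1:S) for (by in 1:S) for (bx in 1:S) {
      bo <- o + (c(bx, by, bz) - 1) * s
      mg <- oracleMeanGradient(g, bo, c(s, s, s))
      h <- h + oracleQuantize(mg, P, t, half)
    }
    feat <- c(feat, list(h))
  }
  # accumulated z-outer / x-inner, i.e. x-fastest cell order
  unlist(feat)
}

# O(n^2) pairwise rank statistic: P(score_pos > score_neg), ties half
oracleAUC <- function(scores, labels) {
  pos <- scores[labels == "positive"]
  neg <- scores[labels == "negative"]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# small deterministic random volume
randomVolume <- function(dims, seed = 1, spacing = c(2, 2, 2)) {
  set.seed(seed)
  PETVolume(array(rnorm(prod(dims)), dims), spacing)
}

# small phantom spec used by the cheaper pipeline tests
smallSpec <- function(...) {
  PhantomSpec(shape = c(40L, 48L, 40L), ...)
}

cohortFeatures <- function(cohort, params = HOGParams()) {
  t(vapply(cohort$bundles,
           function(b) as.numeric(extractDescriptor(b@volume, params)),
           numeric(length(extractDescriptor(cohort$bundles[[1]]@volume, params)))))
}
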