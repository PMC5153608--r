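test_that("cell partition counts, anchoring and error contract", {
  c8 <- partitionCells(c(32, 32, 32), 16)
  expect_length(c8, 8L)
  expect_identical(attr(c8, "gridShape"), c(2L, 2L, 2L))

  c150 <- partitionCells(c(80, 96, 80), 16)
  expect_length(c150, 150L)
  expect_identical(attr(c150, "gridShape"), c(5L, 6L, 5L))

  expect_error(partitionCells(c(10, 10, 10), 16),
               class = "amyloidHOG_error_tooSmall")

  # centered anchoring: 37 = 2*16 + 5 -> offset floor(5/2) = 2, origins 3, 19
  cc <- partitionCells(c(37, 37, 37), 16)
  origins <- t(vapply(cc, function(c) c@origin, integer(3)))
  expect_identical(sort(unique(origins[, 1])), c(3L, 19L))
  # cells are disjoint and exactly k^3
  expect_true(all(vapply(cc, function(c) all(c@size == 16L), logical(1))))
})

test_that("cell histograms follow the quantizer on constant-gradient content", {
  dims <- c(32, 32, 32)
  ramp <- PETVolume(array(rep(seq_len(dims[1]), times = prod(dims[-1])), dims) * 1.0)
  iv <- buildIntegral(computeGradient(ramp))
  poly <- makePolyhedron("icosahedron", half = TRUE)
  cell <- Cuboid(c(9, 9, 9), c(16, 16, 16))  # interior cell

  h1 <- cellHistogram(iv, cell, HOGParams(k = 16, S = 1), poly)
  expect_equal(sqrt(sum(h1^2)), 1, tolerance = 1e-9)
  expect_equal(h1, as.numeric(quantizeGradient(c(1, 0, 0), poly)),
               tolerance = 1e-9)

  # constant gradient: each of the 8 sub-block votes equals the S=1 vote
  h2 <- cellHistogram(iv, cell, HOGParams(k = 16, S = 2), poly)
  expect_equal(h2, 8 * h1, tolerance = 1e-9)

  ivc <- buildIntegral(computeGradient(PETVolume(array(5, dims))))
  expect_identical(cellHistogram(ivc, cell, HOGParams(k = 16, S = 1), poly),
                   numeric(10))
})

test_that("descriptor length follows the cell-count x bin-count formula", {
  v80 <- randomVolume(c(80, 96, 80), seed = 41)
  f <- extractDescriptor(v80, HOGParams(k = 16, S = 1, kind = "icosahedron",
                                        half = TRUE))
  expect_length(f, 1500L)

  v32 <- randomVolume(c(32, 32, 32), seed = 42)
  f2 <- extractDescriptor(v32, HOGParams(k = 16, kind = "dodecahedron",
                                         half = TRUE))
  expect_length(f2, 8L * 6L)

  # formula across assorted parameter combinations
  for (p in list(HOGParams(k = 8, S = 2, kind = "dodecahedron", half = FALSE),
                 HOGParams(k = 4, S = 1, kind = "icosahedron", half = FALSE),
                 HOGParams(k = 12, S = 4, kind = "icosahedron", half = TRUE))) {
    fi <- extractDescriptor(v32, p)
    nb <- nBins(makePolyhedron(p@kind, p@half))
    expect_length(fi, (32L %/% p@k)^3 * nb)
    expect_true(all(fi >= 0))
  }
})

test_that("descriptor equals the loop-based oracle without integral volumes", {
  v <- randomVolume(c(48, 48, 48), seed = 43)
  draws <- list(
    list(k = 16, S = 1, kind = "icosahedron", half = TRUE),
    list(k = 16, S = 2, kind = "icosahedron", half = FALSE),
    list(k = 24, S = 1, kind = "dodecahedron", half = TRUE),
    list(k = 12, S = 2, kind = "dodecahedron", half = FALSE),
    list(k = 8, S = 4, kind = "icosahedron", half = TRUE))
  for (d in draws) {
    p <- HOGParams(k = d$k, S = d$S, kind = d$kind, half = d$half)
    poly <- makePolyhedron(d$kind, d$half)
    got <- as.numeric(extractDescriptor(v, p))
    want <- oracleDescriptor(volData(v), d$k, d$S, faceCenters(poly),
                             projectionThreshold(poly), d$half)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("shifting content by one cell permutes the cell histograms", {
  k <- 8L
  dims <- c(32L, 32L, 32L)
  set.seed(44)
  base <- array(0, dims)
  base[9:16, 9:24, 9:24] <- rnorm(8 * 16 * 16)  # interior content, zero margins
  shifted <- array(0, dims)
  shifted[17:24, 9:24, 9:24] <- base[9:16, 9:24, 9:24]
  p <- HOGParams(k = k, S = 1)
  fA <- extractDescriptor(PETVolume(base), p)
  fB <- extractDescriptor(PETVolume(shifted), p)
  gs <- attr(fA, "gridShape")
  hA <- matrix(fA, ncol = 10, byrow = TRUE)
  hB <- matrix(fB, ncol = 10, byrow = TRUE)
  cellIdx <- expand.grid(ix = 1:gs[1], iy = 1:gs[2], iz = 1:gs[3])
  for (r in seq_len(nrow(cellIdx))) {
    src <- cellIdx[r, ]
    if (src$ix + 1 <= gs[1]) {
      dst <- which(cellIdx$ix == src$ix + 1 & cellIdx$iy == src$iy &
                     cellIdx$iz == src$iz)
      expect_equal(hB[dst, ], hA[r, ], tolerance = 1e-9)
    }
  }
})

test_that("half-orientation descriptors are invariant to intensity inversion", {
  v <- randomVolume(c(32, 32, 32), seed = 45)
  p <- HOGParams(k = 16, S = 1, kind = "icosahedron", half = TRUE)
  fPos <- extractDescriptor(v, p)
  fNeg <- extractDescriptor(PETVolume(-volData(v)), p)
  expect_equal(as.numeric(fPos), as.numeric(fNeg), tolerance = 1e-9)

  # full orientation is NOT inversion invariant (sanity contrast)
  pf <- HOGParams(k = 16, S = 1, kind = "icosahedron", half = FALSE)
  expect_gt(max(abs(extractDescriptor(v, pf) -
                      extractDescriptor(PETVolume(-volData(v)), pf))), 1e-3)
})

test_that("parameter grid enumerates 96 combinations including the optimum", {
  grid <- enumerateParamGrid()
  expect_length(grid, 96L)
  key <- vapply(grid, function(p)
    sprintf("%d_%d_%s_%d", p@k, p@S, p@kind, p@half), character(1))
  expect_identical(anyDuplicated(key), 0L)
  expect_true("16_1_icosahedron_1" %in% key)
  expect_true(all(vapply(grid, function(p) p@k %% p@S == 0L, logical(1))))
  expect_identical(sort(unique(vapply(grid, function(p) p@k, integer(1)))),
                   seq(4L, 32L, by = 4L))
})

test_that("alternative layouts: sub-block concatenation and per-cell L2", {
  v <- randomVolume(c(16, 16, 16), seed = 46)
  pc <- HOGParams(k = 8, S = 2, concatSubblocks = TRUE)
  fc <- extractDescriptor(v, pc)
  expect_length(fc, 8L * 8L * 10L)  # cells x sub-blocks x bins
  # summing concatenated sub-block votes recovers the default layout
  fd <- extractDescriptor(v, HOGParams(k = 8, S = 2))
  perCell <- matrix(fc, ncol = 8 * 10, byrow = TRUE)  # one row per cell
  summed <- t(apply(perCell, 1, function(seg) rowSums(matrix(seg, nrow = 10))))
  expect_equal(as.numeric(t(summed)), as.numeric(fd), tolerance = 1e-9)

  pn <- HOGParams(k = 8, S = 1, normalizeCells = TRUE)
  fn <- extractDescriptor(v, pn)
  norms <- sqrt(rowSums(matrix(fn, ncol = 10, byrow = TRUE)^2))
  expect_true(all(abs(norms - 1) < 1e-6))
})

test_that("feature matrices round-trip through CSV with sidecar parameters", {
  v <- randomVolume(c(16, 16, 16), seed = 47)
  p <- HOGParams(k = 8)
  f <- extractDescriptor(v, p)
  m <- rbind(f, f * 2)
  path <- tempfile(fileext = ".csv")
  writeFeatureMatrix(m, path, params = p, ids = c("a", "b"))
  back <- readFeatureMatrix(path)
  expect_equal(unname(back), unname(m), tolerance = 1e-12)
  expect_identical(colnames(back), names(f))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_identical(side$k, 8L)
})
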