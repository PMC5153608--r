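test_that("polyhedron face sets have the right counts, norms and pairing", {
  cases <- list(
    list(kind = "icosahedron", half = FALSE, n = 20L),
    list(kind = "icosahedron", half = TRUE, n = 10L),
    list(kind = "dodecahedron", half = FALSE, n = 12L),
    list(kind = "dodecahedron", half = TRUE, n = 6L))
  for (cs in cases) {
    p <- makePolyhedron(cs$kind, half = cs$half)
    P <- faceCenters(p)
    expect_identical(nrow(P), cs$n)
    expect_identical(nBins(p), cs$n)
    expect_lt(max(abs(sqrt(rowSums(P^2)) - 1)), 1e-12)
  }
  # full sets come in antipodal pairs; half-set faces have their antipode
  # in the discarded complement
  for (kind in c("icosahedron", "dodecahedron")) {
    Pf <- faceCenters(makePolyhedron(kind, half = FALSE))
    for (i in seq_len(nrow(Pf))) {
      expect_true(any(rowSums(abs(Pf + rep(Pf[i, ], each = nrow(Pf)))) < 1e-9))
    }
    Ph <- faceCenters(makePolyhedron(kind, half = TRUE))
    for (i in seq_len(nrow(Ph))) {
      inHalf <- any(rowSums(abs(Ph + rep(Ph[i, ], each = nrow(Ph)))) < 1e-9)
      expect_false(inHalf)
      inFull <- any(rowSums(abs(Pf + rep(Ph[i, ], each = nrow(Pf)))) < 1e-9)
      expect_true(inFull)
    }
  }
  expect_error(makePolyhedron("tetrahedron"))
})

test_that("projection threshold is the adjacent-face cosine of the full set", {
  for (kind in c("icosahedron", "dodecahedron")) {
    p <- makePolyhedron(kind, half = FALSE)
    P <- faceCenters(p)
    dots <- c()
    for (i in 1:(nrow(P) - 1)) for (j in (i + 1):nrow(P)) {
      dd <- sum(P[i, ] * P[j, ])
      if (abs(dd + 1) > 1e-9) dots <- c(dots, dd)
    }
    expect_equal(projectionThreshold(p), max(dots), tolerance = 1e-12)
    # half mode inherits the full-set threshold by default
    expect_identical(projectionThreshold(makePolyhedron(kind, half = TRUE)),
                     projectionThreshold(p))
  }
  # dodecahedron adjacency cosine is 1/sqrt(5) in closed form
  expect_equal(projectionThreshold(makePolyhedron("dodecahedron")),
               1 / sqrt(5), tolerance = 1e-12)
})

test_that("a face-aligned gradient votes its full magnitude in exactly one bin", {
  for (kind in c("icosahedron", "dodecahedron")) for (half in c(TRUE, FALSE)) {
    p <- makePolyhedron(kind, half = half)
    P <- faceCenters(p)
    for (i in seq_len(nrow(P))) {
      q <- quantizeGradient(3.25 * P[i, ], p)
      expect_equal(unname(q[i]), 3.25, tolerance = 1e-12)
      expect_identical(sum(q != 0), 1L)
    }
  }
})

test_that("votes conserve gradient magnitude and match the loop oracle", {
  p <- makePolyhedron("icosahedron", half = TRUE)
  set.seed(5)
  G <- matrix(rnorm(3000), 1000, 3)
  G <- G / sqrt(rowSums(G^2))
  Q <- quantizeGradient(G, p)
  expect_lt(max(abs(sqrt(rowSums(Q^2)) - 1)), 1e-9)
  expect_true(all(Q >= 0))
  # against the explicit per-face loop
  for (i in sample(1000, 25)) {
    expect_equal(unname(Q[i, ]),
                 oracleQuantize(G[i, ], faceCenters(p), projectionThreshold(p),
                                half = TRUE),
                 tolerance = 1e-12)
  }
  expect_identical(as.numeric(quantizeGradient(c(0, 0, 0), p)), numeric(10))
  expect_error(quantizeGradient(c(1, NA, 0), p),
               class = "amyloidHOG_error_nonfinite")
})

test_that("half-orientation votes are sign-invariant and positively homogeneous", {
  p <- makePolyhedron("dodecahedron", half = TRUE)
  set.seed(6)
  for (i in 1:100) {
    g <- rnorm(3)
    expect_equal(as.numeric(quantizeGradient(g, p)),
                 as.numeric(quantizeGradient(-g, p)), tolerance = 1e-12)
    a <- runif(1, 0.1, 10)
    expect_equal(as.numeric(quantizeGradient(a * g, p)),
                 a * as.numeric(quantizeGradient(g, p)), tolerance = 1e-9)
  }
})

test_that("every nonzero gradient lands in at least one bin over 1e5 directions", {
  set.seed(7)
  G <- matrix(rnorm(3e5), 1e5, 3)
  for (kind in c("icosahedron", "dodecahedron")) {
    for (half in c(TRUE, FALSE)) {
      p <- makePolyhedron(kind, half = half)
      Q <- quantizeGradient(G, p)
      expect_true(all(rowSums(Q) > 0))
      # the polyhedra cover the sphere: no argmax fallbacks expected
      expect_identical(attr(Q, "fallbacks"), 0L)
    }
  }
})

test_that("signed axis symmetries of the face set permute the vote", {
  p <- makePolyhedron("icosahedron", half = FALSE)
  P <- faceCenters(p)
  # cyclic axis rotation and a single-axis sign flip both map the
  # golden-ratio face set onto itself
  transforms <- list(
    function(g) g[c(2, 3, 1)],
    function(g) c(-g[1], g[2], g[3]))
  set.seed(8)
  for (tr in transforms) {
    Ptr <- t(apply(P, 1, tr))
    perm <- vapply(seq_len(nrow(P)), function(i) {
      which(rowSums(abs(P - rep(Ptr[i, ], each = nrow(P)))) < 1e-9)
    }, integer(1))
    expect_identical(sort(perm), seq_len(nrow(P)))  # bijection
    for (i in 1:20) {
      g <- rnorm(3)
      q <- as.numeric(quantizeGradient(g, p))
      qt <- as.numeric(quantizeGradient(tr(g), p))
      expect_equal(qt[perm], q, tolerance = 1e-9)
    }
  }
})

test_that("polyhedron geometry exports to JSON with faces and threshold", {
  p <- makePolyhedron("dodecahedron", half = TRUE)
  path <- tempfile(fileext = ".json")
  polyhedronToJSON(p, path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(j$kind, "dodecahedron")
  expect_identical(j$n_bins, 6L)
  expect_equal(j$threshold, 1 / sqrt(5), tolerance = 1e-12)
  expect_identical(dim(as.matrix(j$faces)), c(6L, 3L))
})
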