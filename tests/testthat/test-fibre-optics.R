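test_that("fibre layouts: degenerate cases, jitter, capacity and determinism", {
  # single fibre sits at the disc centre
  l1 <- generateFibreLayout(1, c(64, 64), jitter = 0, seed = 0)
  expect_equal(unname(positions(l1)[1, ]), c(32, 32))

  # unjittered 7-fibre bundle: centre plus a hexagonal ring, all
  # nearest-neighbour distances equal
  l7 <- generateFibreLayout(7, c(64, 64), jitter = 0, seed = 0)
  d <- as.matrix(dist(positions(l7)))
  nn <- apply(d + diag(Inf, 7), 1, min)
  expect_lt(max(nn) - min(nn), 1e-9)

  # jittered layout: irregular (CV of nn distance > 0) yet inside the FOV
  l <- generateFibreLayout(200, c(128, 128), jitter = 0.3, seed = 7)
  p <- positions(l)
  d2 <- (p[, 1] - 64)^2 + (p[, 2] - 64)^2
  expect_true(all(d2 < 64^2))
  dm <- as.matrix(dist(p))
  nn <- apply(dm + diag(Inf, 200), 1, min)
  expect_gt(sd(nn) / mean(nn), 0)
  expect_gt(min(nn), 0)

  # determinism and capacity error
  expect_equal(positions(generateFibreLayout(50, c(64, 64), 0.3, seed = 3)),
               positions(generateFibreLayout(50, c(64, 64), 0.3, seed = 3)))
  expect_error(generateFibreLayout(10000, c(32, 32), 0, 0), "capacity")
})

test_that("Voronoi maps equal the brute-force nearest-fibre assignment", {
  # single fibre: every FOV pixel labelled 0
  l1 <- generateFibreLayout(1, c(16, 16), jitter = 0, seed = 0)
  vm1 <- computeVoronoiMap(l1, c(16, 16))
  lab <- cellLabels(vm1)
  expect_true(all(lab[lab >= 0] == 0L))

  # two fibres on a horizontal line: boundary is the vertical bisector
  l2 <- FibreLayout(rbind(c(16, 32), c(48, 32)), c(32, 32), 32)
  vm2 <- computeVoronoiMap(l2, c(64, 64))
  lab <- cellLabels(vm2)
  xs <- matrix(rep(seq_len(64) - 0.5, each = 64), 64)
  expect_true(all(lab[lab >= 0 & xs < 32] == 0L))
  expect_true(all(lab[lab >= 0 & xs > 32] == 1L))

  # random layouts vs exhaustive scan; cell sizes account for all FOV pixels
  for (seed in 1:3) {
    l <- generateFibreLayout(10, c(32, 32), jitter = 0.4, seed = seed)
    vm <- computeVoronoiMap(l, c(32, 32))
    expect_identical(cellLabels(vm), bfVoronoiLabels(l, c(32, 32)))
    expect_identical(sum(cellSizes(vm)), sum(cellLabels(vm) >= 0L))
  }
})

test_that("signal extraction averages each Voronoi cell", {
  l <- generateFibreLayout(4, c(8, 8), jitter = 0.2, seed = 1)
  vm <- computeVoronoiMap(l, c(8, 8))

  # constant image
  s <- extractFibreSignals(matrix(0.7, 8, 8), vm)
  expect_equal(signalValues(s)[seq_len(nFibres(s))], rep(0.7, nFibres(s)))

  # two-fibre bisector with distinct halves
  l2 <- FibreLayout(rbind(c(2, 4), c(6, 4)), c(4, 4), 4)
  vm2 <- computeVoronoiMap(l2, c(8, 8))
  img <- cbind(matrix(0.2, 8, 4), matrix(0.8, 8, 4))
  expect_equal(signalValues(extractFibreSignals(img, vm2))[1:2], c(0.2, 0.8))

  # random image vs loop oracle
  img <- matrix(runif(64), 8, 8)
  got <- signalValues(extractFibreSignals(img, vm))[seq_len(4)]
  expect_equal(got, bfCellMeans(img, cellLabels(vm), 4))

  expect_error(extractFibreSignals(matrix(0, 4, 4), vm), "shape")
})

test_that("fibre noise follows the stated additive/multiplicative model", {
  s <- FibreSignalVector(c(0.2, 0.5, 0.9))
  expect_identical(addFibreNoise(s, noiseParams(0, 0, seed = 1)), s)

  n <- 1e5
  add <- addFibreNoise(FibreSignalVector(rep(1, n)),
                       noiseParams(0.1, 0, seed = 2))
  v <- signalValues(add)[seq_len(n)]
  expect_lt(abs(mean(v) - 1), 3 * 0.1 / sqrt(n))
  expect_lt(abs(sd(v) - 0.1) / 0.1, 0.05)

  mult <- addFibreNoise(FibreSignalVector(rep(2, n)),
                        noiseParams(0, 0.1, seed = 3))
  expect_lt(abs(sd(signalValues(mult)[seq_len(n)]) - 0.2) / 0.2, 0.05)

  # determinism and non-negativity
  a <- addFibreNoise(s, noiseParams(0.3, 0.1, seed = 9))
  b <- addFibreNoise(s, noiseParams(0.3, 0.1, seed = 9))
  expect_identical(signalValues(a), signalValues(b))
  expect_true(all(signalValues(a) >= 0))
})

test_that("Delaunay reconstruction is exact for constants and affine fields", {
  l <- generateFibreLayout(20, c(48, 48), jitter = 0.3, seed = 7)
  pos <- positions(l)

  # constants are preserved everywhere inside the FOV
  lr <- reconstructLR(FibreSignalVector(rep(0.4, 20)), l, c(48, 48))
  m <- frameData(lr)
  mask <- (outer(rep(1, 48), seq_len(48) - 0.5) - 24)^2 +
          (outer(seq_len(48) - 0.5, rep(1, 48)) - 24)^2 <= 24^2
  expect_lt(max(abs(m[mask] - 0.4)), 1e-12)
  expect_true(all(m[!mask] == 0))

  # affine fields are reproduced exactly inside the convex hull
  f <- function(x, y) 0.01 * x + 0.02 * y + 0.1
  lr <- reconstructLR(FibreSignalVector(f(pos[, 1], pos[, 2])), l, c(48, 48))
  m <- frameData(lr)
  hull <- chull(pos); hp <- pos[hull, ]
  err <- 0
  for (r in 1:48) for (c in 1:48) {
    x <- c - 0.5; y <- r - 0.5
    ok <- TRUE
    for (i in seq_len(nrow(hp))) {
      j <- i %% nrow(hp) + 1
      if ((hp[j, 1] - hp[i, 1]) * (y - hp[i, 2]) -
          (hp[j, 2] - hp[i, 2]) * (x - hp[i, 1]) < 1e-7) { ok <- FALSE; break }
    }
    if (ok && mask[r, c]) err <- max(err, abs(m[r, c] - f(x, y)))
  }
  expect_lt(err, 1e-9)

  expect_error(reconstructLR(FibreSignalVector(1:3),
                             FibreLayout(cbind(c(10, 20, 30), c(16, 16, 16)),
                                         c(32, 32), 32),
                             c(64, 64)),
               "collinear")
})

test_that("reconstruction agrees with exhaustive triangle location", {
  l <- generateFibreLayout(20, c(48, 48), jitter = 0.35, seed = 12)
  pos <- positions(l)
  vals <- withr::with_seed(1, runif(20))
  m <- frameData(reconstructLR(FibreSignalVector(vals), l, c(48, 48)))
  tri <- fibreSR:::delaunayTriangulate(pos)
  checked <- 0L
  for (r in seq(2, 48, by = 3)) for (c in seq(2, 48, by = 3)) {
    x <- c - 0.5; y <- r - 0.5
    ref <- bfBarycentric(tri, pos, vals, x, y)
    if (!is.na(ref) && (x - 24)^2 + (y - 24)^2 <= 24^2) {
      expect_lt(abs(m[r, c] - ref), 1e-9)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 50L)
})

test_that("the acquisition chain composes and is reproducible", {
  l <- generateFibreLayout(40, c(48, 48), jitter = 0.3, seed = 2)
  hr <- generateTextureHR(64, seed = 4)
  hr48 <- ImageFrame(frameData(hr)[1:48, 1:48], role = "HR")

  # zero noise: simulate == reconstruct(extract(hr))
  sim <- simulateLRfromHR(hr48, l, noiseParams(0, 0, seed = 1))
  vm <- computeVoronoiMap(l, c(48, 48))
  direct <- reconstructLR(extractFibreSignals(hr48, vm), l, c(48, 48))
  expect_identical(frameData(sim$lr), frameData(direct))

  # fixed seed: byte-identical repetition
  a <- simulateLRfromHR(hr48, l, noiseParams(0.02, 0.05, seed = 6))
  b <- simulateLRfromHR(hr48, l, noiseParams(0.02, 0.05, seed = 6))
  expect_identical(frameData(a$lr), frameData(b$lr))
  expect_identical(signalValues(a$signals), signalValues(b$signals))

  # constant HR with zero noise stays constant inside the FOV
  simc <- simulateLRfromHR(matrix(0.6, 48, 48), l, noiseParams(0, 0, 1))
  mc <- frameData(simc$lr)
  mask <- cellLabels(vm) >= 0L
  expect_lt(max(abs(mc[mask] - 0.6)), 1e-12)
})

test_that("painting each cell with its own constant inverts signal extraction", {
  l <- generateFibreLayout(15, c(32, 32), jitter = 0.3, seed = 8)
  vm <- computeVoronoiMap(l, c(32, 32))
  vals <- withr::with_seed(2, runif(15))
  img <- matrix(0, 32, 32)
  lab <- cellLabels(vm)
  img[lab >= 0L] <- vals[lab[lab >= 0L] + 1L]
  got <- signalValues(extractFibreSignals(img, vm))[1:15]
  expect_equal(got, vals, tolerance = 1e-12)
})
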