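test_that("Voronoi vectorization: normalization, padding and degenerate rules", {
  l2 <- FibreLayout(rbind(c(2, 4), c(6, 4)), c(4, 4), 4)
  vm2 <- computeVoronoiMap(l2, c(8, 8))

  # constant patch: degenerate min = max rule maps every real entry to 0
  v <- voronoiVectorize(matrix(0.3, 8, 8), vm2, 4)
  expect_equal(signalValues(v), rep(0, 4))
  expect_true(isNormalized(v))

  # two-cell patch with means 0.2 / 0.8
  img <- cbind(matrix(0.2, 8, 4), matrix(0.8, 8, 4))
  expect_equal(signalValues(voronoiVectorize(img, vm2, 4)), c(0, 1, 0, 0))

  # padding too small
  expect_error(voronoiVectorize(img, vm2, 1), "paddedLen")
})

test_that("Voronoi vectorization matches a per-pixel loop oracle", {
  l <- generateFibreLayout(9, c(16, 16), jitter = 0.3, seed = 4)
  vm <- computeVoronoiMap(l, c(16, 16))
  img <- withr::with_seed(3, matrix(runif(256), 16, 16))
  v <- voronoiVectorize(img, vm, 12)

  means <- bfCellMeans(img, cellLabels(vm), 9)
  present <- which(!is.na(means))
  mn <- min(means[present]); mx <- max(means[present])
  ref <- c((means[present] - mn) / (mx - mn), rep(0, 12 - length(present)))
  expect_equal(signalValues(v), ref, tolerance = 1e-12)
  expect_identical(paddedLength(v), 12L)
  expect_equal(signalValues(v)[(nFibres(v) + 1):12], rep(0, 12 - nFibres(v)))
})

test_that("acquisition vectors normalize raw signals or fall back to the patch", {
  # raw path: min-max of an arithmetic sequence
  raw <- FibreSignalVector(c(1, 3, 5))
  v <- acquisitionVector(rawSignals = raw, paddedLen = 4)
  expect_equal(signalValues(v), c(0, 0.5, 1, 0))

  # fallback path: constant LR patch -> all zeros
  l <- generateFibreLayout(5, c(12, 12), jitter = 0.2, seed = 2)
  vm <- computeVoronoiMap(l, c(12, 12))
  vf <- acquisitionVector(lr = matrix(0.5, 12, 12), vmap = vm, paddedLen = 6)
  expect_equal(signalValues(vf), rep(0, 6))

  expect_error(acquisitionVector(paddedLen = 4), "rawSignals")
})

test_that("raw and fallback acquisition vectors agree on interior fibres", {
  # zero-noise simulation: vectorizing the reconstructed LR approximates the
  # raw signal path up to interpolation error
  l <- generateFibreLayout(200, c(128, 128), jitter = 0.3, seed = 0)
  hr <- generateTextureHR(128, seed = 0)
  sim <- simulateLRfromHR(hr, l, noiseParams(0, 0, seed = 0))
  NF <- 200L
  vRaw <- acquisitionVector(vmap = sim$vmap, rawSignals = sim$signals,
                            paddedLen = NF)
  vRec <- voronoiVectorize(sim$lr, sim$vmap, NF)
  # interior fibres: away from the bundle boundary where extrapolation acts
  pos <- positions(l)
  d <- sqrt((pos[, 1] - 64)^2 + (pos[, 2] - 64)^2)
  interior <- which(d < 0.8 * fovRadius(l))
  dif <- abs(signalValues(vRaw)[interior] - signalValues(vRec)[interior])
  expect_lt(mean(dif), 0.05)
})

test_that("normalization is idempotent and painting cells is a fixed point", {
  l <- generateFibreLayout(12, c(24, 24), jitter = 0.3, seed = 6)
  vm <- computeVoronoiMap(l, c(24, 24))
  img <- withr::with_seed(5, matrix(runif(576), 24, 24))
  v1 <- voronoiVectorize(img, vm, 14)

  # idempotence: re-normalizing the normalized vector changes nothing
  n <- nFibres(v1)
  renorm <- acquisitionVector(
    rawSignals = FibreSignalVector(signalValues(v1)[seq_len(n)]),
    paddedLen = 14)
  expect_equal(signalValues(renorm), signalValues(v1), tolerance = 1e-12)

  # painting each cell with its vector entry and re-vectorizing returns the
  # same vector exactly
  painted <- matrix(0, 24, 24)
  lab <- cellLabels(vm)
  ids <- fibreIds(v1)
  entry <- signalValues(v1)
  lut <- rep(NA_real_, 12)
  lut[ids + 1L] <- entry[seq_len(n)]
  painted[lab >= 0L] <- lut[lab[lab >= 0L] + 1L]
  v2 <- voronoiVectorize(painted, vm, 14)
  expect_identical(signalValues(v2), signalValues(v1))
})

test_that("cropped Voronoi maps preserve counts and drive patch vectors", {
  l <- generateFibreLayout(40, c(64, 64), jitter = 0.3, seed = 9)
  vm <- computeVoronoiMap(l, c(64, 64))
  sub <- cropVoronoiMap(vm, 16, 16, 16)
  lab <- cellLabels(sub)
  expect_identical(dim(lab), c(16L, 16L))
  expect_identical(lab, cellLabels(vm)[17:32, 17:32])
  expect_identical(sum(cellSizes(sub)), sum(lab >= 0L))
  # vector over the window uses only visible fibres
  v <- voronoiVectorize(matrix(runif(256), 16, 16), sub,
                        sum(cellSizes(sub) > 0L))
  expect_identical(nFibres(v), sum(cellSizes(sub) > 0L))
})
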