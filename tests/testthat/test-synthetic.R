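test_that("texture generation is deterministic and parameter-sensitive", {
  a <- generateTextureHR(64, seed = 3)
  b <- generateTextureHR(64, seed = 3)
  expect_identical(frameData(a), frameData(b))
  expect_true(all(frameData(a) >= 0 & frameData(a) <= 1))

  # no blobs + very long correlation length: near-flat frame, much less
  # contrast than the default texture
  flat <- generateTextureHR(64, list(corrLength = 64, blobDensity = 0,
                                     contrast = 0.6), seed = 3)
  expect_lt(metricGCF(flat), metricGCF(a))

  # doubling the blob density roughly doubles the blob-pixel fraction,
  # estimated as the bright-pixel excess over the blob-free background
  frac <- function(dens) {
    mean(vapply(1:20, function(s) {
      f <- generateTextureHR(64, list(corrLength = 6, blobDensity = dens,
                                      contrast = 0.6), seed = 100 + s)
      mean(frameData(f) > 0.8)
    }, 0))
  }
  r <- (frac(8) - frac(0)) / (frac(4) - frac(0))
  expect_gt(r, 1.4)
  expect_lt(r, 2.9)
})

test_that("natural stand-ins are sharper than tissue textures", {
  pats <- generateNaturalStandin(20, 64, seed = 1)
  expect_identical(frameData(pats[[1]]),
                   frameData(generateNaturalStandin(1, 64, seed = 1)[[1]]))
  expect_true(all(vapply(pats, function(p)
    all(frameData(p) >= 0 & frameData(p) <= 1), TRUE)))

  # mean radial power above the Nyquist/4 band exceeds the tissue statistic
  highPower <- function(m) {
    n <- nrow(m)
    P <- Mod(fft(m - mean(m)))^2
    fr <- pmin(0:(n - 1), n - 0:(n - 1)) / n
    band <- outer(fr^2, fr^2, `+`) > (0.25 / 2)^2
    mean(P[band]) / mean(P)
  }
  hpNat <- mean(vapply(pats, function(p) highPower(frameData(p)), 0))
  tis <- lapply(1:20, function(s) generateTextureHR(64, seed = 200 + s))
  hpTis <- mean(vapply(tis, function(p) highPower(frameData(p)), 0))
  expect_gt(hpNat, hpTis)
})

test_that("study generation: counts, grouping and reproducibility", {
  study <- tinyStudy(seed = 5, nPatients = 4, videosPerPatient = 2,
                     framesPerVideo = 3, frameSize = 96, nFibres = 60)
  expect_length(study$hr, 24L)
  expect_length(study$lr, 24L)
  expect_identical(nrow(study$metadata), 24L)
  expect_identical(sort(unique(study$metadata$clinical_setting)),
                   c("colon", "oesophagus"))
  expect_identical(length(unique(study$metadata$video_id)), 8L)

  # byte-identical regeneration
  study2 <- tinyStudy(seed = 5, nPatients = 4, videosPerPatient = 2,
                      framesPerVideo = 3, frameSize = 96, nFibres = 60)
  expect_identical(lapply(study$lr, frameData), lapply(study2$lr, frameData))
  expect_identical(lapply(study$signals, signalValues),
                   lapply(study2$signals, signalValues))

  # CS1/CS2 splits on the metadata leak no group (the tiny cohort triggers
  # small-stratum warnings, which are not under test here)
  for (key in c("video_id", "patient_id")) {
    sp <- suppressWarnings(
      splitDataset(study$metadata, splitPlan(groupKey = key), seed = 2))
    for (g in unique(study$metadata[[key]])) {
      ids <- study$metadata$frame_id[study$metadata[[key]] == g]
      hit <- vapply(sp, function(s) any(ids %in% s), TRUE)
      expect_identical(sum(hit), 1L)
    }
  }
})

test_that("unpaired mode with zero misalignment degenerates to paired", {
  specP <- syntheticStudySpec(nPatients = 1, videosPerPatient = 1,
                              framesPerVideo = 2, frameSize = 96,
                              nFibres = 50, noise = noiseParams(0, 0, 1),
                              misalignment = list(maxShift = 0,
                                                  maxRotation = 0),
                              seed = 3)
  a <- generateStudy(specP, "paired")
  b <- generateStudy(specP, "unpaired")
  expect_equal(lapply(a$lr, frameData), lapply(b$lr, frameData),
               tolerance = 1e-12)
})

test_that("zero-noise paired studies satisfy the cycle fixed point", {
  study <- tinyStudy(seed = 7, noise = noiseParams(0, 0, 1),
                     frameSize = 96, nFibres = 60, nPatients = 1,
                     framesPerVideo = 1)
  fid <- names(study$lr)[1]
  NF <- 60L
  vRaw <- acquisitionVector(vmap = study$vmap,
                            rawSignals = study$signals[[fid]],
                            paddedLen = NF)

  # painting each cell with its signal and re-vectorizing gives l_vec = 0
  lab <- cellLabels(study$vmap)
  n <- nFibres(vRaw)
  lut <- rep(0, 60); lut[fibreIds(vRaw) + 1L] <- signalValues(vRaw)[seq_len(n)]
  painted <- matrix(0, 96, 96)
  painted[lab >= 0L] <- lut[lab[lab >= 0L] + 1L]
  vPaint <- voronoiVectorize(painted, study$vmap, NF)
  expect_identical(lossVec(vRaw, vPaint), 0)

  # textured frames: reconstruction-then-vectorization stays close to the
  # stored acquisition vector away from the bundle boundary
  vRec <- voronoiVectorize(study$lr[[fid]], study$vmap, NF)
  pos <- positions(study$layout)
  ctr <- fovCenter(study$layout)
  d <- sqrt((pos[, 1] - ctr[1])^2 + (pos[, 2] - ctr[2])^2)
  interior <- which(d < 0.8 * fovRadius(study$layout))
  dif <- abs(signalValues(vRaw)[interior] - signalValues(vRec)[interior])
  expect_lt(mean(dif), 0.05)
})

test_that("training samples share one padded length and aligned windows", {
  study <- tinyStudy(seed = 9, frameSize = 96, nFibres = 60,
                     nPatients = 2, framesPerVideo = 1)
  st <- studyTrainingSamples(study, patchSize = 24L)
  expect_gt(length(st$samples), 0L)
  for (s in st$samples) {
    expect_identical(paddedLength(s$vLr), st$NF)
    expect_identical(dim(s$lr), dim(cellLabels(s$vmap)))
    expect_identical(dim(s$lr), dim(s$hr))
  }
})
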