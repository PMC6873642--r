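test_that("sequence preprocessing: z-score then per-frame min-max", {
  # single frame of equally frequent {0, 1}: stage 1 gives +-1, stage 2 {0, 1}
  f <- matrix(c(0, 1), 16, 16)
  out <- preprocessSequence(list(f))[[1]]
  expect_identical(sort(unique(as.vector(frameData(out)))), c(0, 1))

  # per-frame min 0 / max 1 postcondition
  frames <- withr::with_seed(1, lapply(1:3, function(i)
    matrix(runif(64, 0, i), 8, 8)))
  outs <- preprocessSequence(frames)
  for (o in outs) {
    expect_equal(min(frameData(o)), 0)
    expect_equal(max(frameData(o)), 1)
  }

  # equals an independent two-stage reimplementation
  allv <- unlist(lapply(frames, as.vector))
  mu <- mean(allv); sdv <- sd(allv)
  for (i in 1:3) {
    z <- (frames[[i]] - mu) / sdv
    ref <- (z - min(z)) / (max(z) - min(z))
    expect_equal(frameData(outs[[i]]), ref, tolerance = 1e-12)
  }

  expect_error(preprocessSequence(list(matrix(0.5, 4, 4))), "variance")
})

test_that("patch extraction tiles the FOV interior", {
  # full 512x512 frame with no mask: (512/64)^2 patches
  big <- matrix(0, 512, 512)
  expect_length(extractPatches(big, NULL, 64L), 64L)

  # frame equal to the patch size returns exactly itself
  f <- matrix(runif(64 * 64), 64, 64)
  ps <- extractPatches(f, NULL, 64L)
  expect_length(ps, 1L)
  expect_identical(frameData(ps[[1]]), f)

  # circular mask: kept patches equal the brute-force mask check
  mask <- fibreSR:::fovMask(c(128, 128), c(64, 64), 64)
  got <- extractPatches(matrix(1, 128, 128), mask, 32L)
  cnt <- 0L
  for (r0 in seq(0, 96, by = 32)) for (c0 in seq(0, 96, by = 32))
    if (all(mask[r0 + 1:32, c0 + 1:32])) cnt <- cnt + 1L
  expect_length(got, cnt)
  for (p in got) {
    off <- attr(p, "offset")
    expect_true(all(mask[off[1] + 1:32, off[2] + 1:32]))
  }
})

test_that("target domains: res block-averaging, nat membership, syn pairing", {
  # res on a constant region stays constant
  lrConst <- matrix(0.4, 256, 256)
  res <- buildTargetDomain("res", list(lr = list(lrConst)), patchSize = 64L)
  expect_length(res, 1L)
  expect_equal(frameData(res[[1]]), matrix(0.4, 64, 64), tolerance = 1e-12)

  # res on a checkerboard whose period matches the averaging window: every
  # 4x4 area average covers one full period and yields the two-tone mean
  cb <- matrix(0, 256, 256)
  blk <- (row(cb) - 1) %/% 2 + (col(cb) - 1) %/% 2
  cb[] <- ifelse(blk %% 2 == 0, 0.2, 0.8)
  res <- buildTargetDomain("res", list(lr = list(cb)), patchSize = 64L)
  expect_equal(frameData(res[[1]]), matrix(0.5, 64, 64), tolerance = 1e-12)

  # nat: every patch is patchSize^2 and cut from the given images
  imgs <- withr::with_seed(2, lapply(1:3, function(i)
    matrix(runif(96 * 96), 96, 96)))
  nat <- buildTargetDomain("nat", list(nat = imgs), patchSize = 64L)
  expect_length(nat, 3L)
  for (i in 1:3)
    expect_identical(frameData(nat[[i]]), imgs[[i]][1:64, 1:64])

  # syn records the aligned LR patch
  syn <- buildTargetDomain("syn", list(hr = imgs[1], lr = imgs[2]),
                           patchSize = 64L)
  expect_identical(frameData(attr(syn[[1]], "pairedLR")), imgs[[2]][1:64, 1:64])

  expect_error(buildTargetDomain("bogus", list()), "unknown")
})

test_that("grouped splits are exclusive, stratified and deterministic", {
  # 10 single-frame videos: roughly 7 / 1-2 / 1-2, no video straddles subsets
  md <- data.frame(frame_id = sprintf("f%02d", 1:10),
                   video_id = sprintf("v%02d", 1:10),
                   patient_id = rep("p1", 10),
                   clinical_setting = rep("colon", 10))
  sp <- suppressWarnings(
    splitDataset(md, splitPlan(groupKey = "video_id"), seed = 1))
  expect_setequal(unlist(sp), md$frame_id)
  expect_identical(length(sp$train), 7L)
  expect_true(length(sp$val) >= 1L && length(sp$test) >= 1L)

  # single patient under CS2: everything lands in one subset, flagged
  w <- capture_warnings(
    sp1 <- splitDataset(md, splitPlan(groupKey = "patient_id"), seed = 1))
  expect_true(any(grepl("empty", w)))
  expect_true(any(grepl("fewer than 3 groups", w)))
  sizes <- lengths(sp1)
  expect_identical(sort(unname(sizes)), c(0L, 0L, 10L))

  # larger cohort: determinism, exclusivity, stratification
  md2 <- withr::with_seed(3, {
    pats <- sprintf("p%02d", 1:20)
    data.frame(frame_id = sprintf("f%03d", 1:100),
               video_id = sprintf("v%03d", rep(1:50, each = 2)),
               patient_id = rep(pats, each = 5),
               clinical_setting = rep(c("colon", "oesophagus"), each = 50))
  })
  a <- splitDataset(md2, splitPlan(groupKey = "patient_id"), seed = 9)
  b <- splitDataset(md2, splitPlan(groupKey = "patient_id"), seed = 9)
  expect_identical(a, b)
  for (pat in unique(md2$patient_id)) {
    inSub <- vapply(a, function(ids)
      any(md2$frame_id[md2$patient_id == pat] %in% ids), TRUE)
    expect_identical(sum(inSub), 1L)
  }
  # stratification: each setting close to its target fractions
  for (s in c("colon", "oesophagus")) {
    ids <- md2$frame_id[md2$clinical_setting == s]
    frac <- length(intersect(a$train, ids)) / length(ids)
    expect_gt(frac, 0.5); expect_lt(frac, 0.9)
  }
})
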