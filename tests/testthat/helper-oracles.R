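# Brute-force oracles used across the suite. Deliberately written as plain
# per-pixel loops, independent of the vectorised implementations they check.

# nearest-fibre label image by exhaustive per-pixel scan (0-based, -1 outside)
bfVoronoiLabels <- function(layout, gridShape) {
  pos <- positions(layout)
  ctr <- fovCenter(layout); R <- fovRadius(layout)
  lab <- matrix(-1L, gridShape[1], gridShape[2])
  for (r in seq_len(gridShape[1])) for (c in seq_len(gridShape[2])) {
    x <- c - 0.5; y <- r - 0.5
    if ((x - ctr[1])^2 + (y - ctr[2])^2 <= R^2) {
      d2 <- (x - pos[, 1])^2 + (y - pos[, 2])^2
      lab[r, c] <- which.min(d2) - 1L
    }
  }
  lab
}

# per-label means by an independent loop over pixels
bfCellMeans <- function(img, labels, nf) {
  sums <- numeric(nf); cnt <- integer(nf)
  for (i in seq_along(labels)) {
    l <- labels[i]
    if (l >= 0L) {
      sums[l + 1L] <- sums[l + 1L] + img[i]
      cnt[l + 1L] <- cnt[l + 1L] + 1L
    }
  }
  ifelse(cnt > 0L, sums / pmax(cnt, 1L), NA_real_)
}

# point-in-triangle barycentric interpolation by exhaustive search over the
# triangle list; NA where no triangle contains the point
bfBarycentric <- function(tri, pos, vals, x, y) {
  for (k in seq_len(nrow(tri))) {
    a <- tri[k, 1]; b <- tri[k, 2]; cc <- tri[k, 3]
    det <- (pos[b, 2] - pos[cc, 2]) * (pos[a, 1] - pos[cc, 1]) +
           (pos[cc, 1] - pos[b, 1]) * (pos[a, 2] - pos[cc, 2])
    l1 <- ((pos[b, 2] - pos[cc, 2]) * (x - pos[cc, 1]) +
           (pos[cc, 1] - pos[b, 1]) * (y - pos[cc, 2])) / det
    l2 <- ((pos[cc, 2] - pos[a, 2]) * (x - pos[cc, 1]) +
           (pos[a, 1] - pos[cc, 1]) * (y - pos[cc, 2])) / det
    l3 <- 1 - l1 - l2
    if (l1 >= -1e-9 && l2 >= -1e-9 && l3 >= -1e-9)
      return(l1 * vals[a] + l2 * vals[b] + l3 * vals[cc])
  }
  NA_real_
}

# plain double-loop SSIM with an 11x11 Gaussian window (valid region)
bfSSIM <- function(a, b, n = 11L, s = 1.5) {
  x <- seq_len(n) - (n + 1) / 2
  g1 <- exp(-x^2 / (2 * s^2)); g1 <- g1 / sum(g1)
  W <- outer(g1, g1)
  C1 <- 1e-4; C2 <- 9e-4
  H <- nrow(a); Wd <- ncol(a)
  vals <- c()
  for (r in seq_len(H - n + 1L)) for (c in seq_len(Wd - n + 1L)) {
    wa <- a[r:(r + n - 1L), c:(c + n - 1L)]
    wb <- b[r:(r + n - 1L), c:(c + n - 1L)]
    m1 <- sum(W * wa); m2 <- sum(W * wb)
    v1 <- sum(W * wa^2) - m1^2; v2 <- sum(W * wb^2) - m2^2
    cv <- sum(W * wa * wb) - m1 * m2
    vals <- c(vals, (2 * m1 * m2 + C1) * (2 * cv + C2) /
                     ((m1^2 + m2^2 + C1) * (v1 + v2 + C2)))
  }
  mean(vals)
}

# direct per-pixel global contrast factor
bfGCF <- function(m) {
  blockMeanLoop <- function(m, b) {
    H2 <- nrow(m) %/% b; W2 <- ncol(m) %/% b
    if (H2 < 1L || W2 < 1L) return(NULL)
    out <- matrix(0, H2, W2)
    for (i in seq_len(H2)) for (j in seq_len(W2))
      out[i, j] <- mean(m[((i - 1) * b + 1):(i * b), ((j - 1) * b + 1):(j * b)])
    out
  }
  total <- 0
  for (lev in 1:9) {
    b <- 2^(lev - 1)
    ds <- if (b == 1) m else blockMeanLoop(m, b)
    ci <- 0
    if (!is.null(ds) && nrow(ds) >= 2 && ncol(ds) >= 2) {
      L <- 100 * sqrt(ds^2.2)
      acc <- 0
      for (r in seq_len(nrow(ds))) for (c in seq_len(ncol(ds))) {
        s <- 0; k <- 0
        if (r > 1) { s <- s + abs(L[r, c] - L[r - 1, c]); k <- k + 1 }
        if (r < nrow(ds)) { s <- s + abs(L[r, c] - L[r + 1, c]); k <- k + 1 }
        if (c > 1) { s <- s + abs(L[r, c] - L[r, c - 1]); k <- k + 1 }
        if (c < ncol(ds)) { s <- s + abs(L[r, c] - L[r, c + 1]); k <- k + 1 }
        acc <- acc + s / k
      }
      ci <- acc / length(ds)
    }
    w <- (-0.406385 * lev / 9 + 0.334573) * lev / 9 + 0.0877526
    total <- total + w * ci
  }
  total
}

# tiny paired study shared by several tests
tinyStudy <- function(seed = 5L, noise = noiseParams(0, 0, seed = seed),
                      frameSize = 96L, nFibres = 60L,
                      nPatients = 2L, videosPerPatient = 1L,
                      framesPerVideo = 2L, mode = "paired") {
  generateStudy(syntheticStudySpec(
    nPatients = nPatients, videosPerPatient = videosPerPatient,
    framesPerVideo = framesPerVideo, frameSize = frameSize,
    nFibres = nFibres, noise = noise, seed = seed), mode = mode)
}

# Tot_cs cells printed in the results tables: ssim, dgcf_hr, tot_cs
tableTotCsCells <- function() {
  rbind(
    # target-domain comparison, CS1 then CS2 (syn, orig, res, nat)
    data.frame(ssim = c(0.90, 0.91, 0.87, 0.86), dgcf = c(0.01, 0.38, -0.13, 0.66),
               tot = c(0.52, 0.63, 0.44, 0.64)),
    data.frame(ssim = c(0.91, 0.91, 0.87, 0.86), dgcf = c(-0.10, 0.24, -0.26, 0.51),
               tot = c(0.49, 0.59, 0.41, 0.61)),
    # method comparison on the clinical set, CS1 then CS2
    # (proposed, supervised EBSR, variational Bayes, Wiener, sharpening)
    data.frame(ssim = c(0.86, 0.88, 0.86, 0.83, 0.62), dgcf = c(0.66, 0.42, 0.27, -0.00, 1.34),
               tot = c(0.64, 0.61, 0.54, 0.42, 0.53)),
    data.frame(ssim = c(0.86, 0.89, 0.88, 0.85, 0.63), dgcf = c(0.51, 0.38, 0.21, -0.15, 1.32),
               tot = c(0.61, 0.60, 0.54, 0.41, 0.54)),
    # method comparison on the simulated set, CS1 then CS2
    data.frame(ssim = c(0.90, 0.93, 0.89, 0.88, 0.66), dgcf = c(0.60, 0.45, 0.13, -0.21, 1.03),
               tot = c(0.68, 0.68, 0.54, 0.43, 0.50)),
    data.frame(ssim = c(0.91, 0.92, 0.90, 0.89, 0.65), dgcf = c(0.50, 0.52, 0.11, -0.28, 1.08),
               tot = c(0.66, 0.68, 0.54, 0.42, 0.50))
  )
}
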