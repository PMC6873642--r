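#' Noise parameters for the fibre-signal model
#'
#' The simulator corrupts each clean fibre signal \code{fs} with independent
#' multiplicative and additive Gaussian terms,
#' \code{nfs = fs * (1 + m) + a}, \code{m ~ N(0, sigmaMult^2)},
#' \code{a ~ N(0, sigmaAdd^2)}, and clips negative results to zero
#' (fluorescence counts are non-negative). With both sigmas zero the signals
#' pass through untouched.
#'
#' @param sigmaAdd standard deviation of the additive term, in signal units.
#' @param sigmaMult standard deviation of the multiplicative term,
#'   dimensionless.
#' @param seed integer seed making the draw reproducible.
#' @return a validated list of class \code{NoiseParams}.
#' @export
noiseParams <- function(sigmaAdd = 0.02, sigmaMult = 0.05, seed = 0L) {
  stopifnot(sigmaAdd >= 0, sigmaMult >= 0)
  structure(list(sigmaAdd = sigmaAdd, sigmaMult = sigmaMult,
                 seed = as.integer(seed)),
            class = "NoiseParams")
}

#' Generate a jittered hexagonal fibre bundle layout
#'
#' Builds a fibre bundle as a hexagonal lattice filling the disc inscribed in
#' the pixel grid, with each fibre centre perturbed by uniform jitter. Real
#' bundles pack tens of thousands of fibres quasi-hexagonally but irregularly;
#' the jitter fraction controls that irregularity.
#'
#' @param nFibres number of fibres (>= 1).
#' @param gridShape integer \code{(rows, cols)} of the target pixel grid.
#' @param jitter jitter amplitude as a fraction of the lattice pitch, in
#'   \code{[0, 0.5)} so fibres remain pairwise distinct.
#' @param seed integer seed for the jitter draw.
#' @return a \linkS4class{FibreLayout}.
#' @examples
#' lay <- generateFibreLayout(7, c(64, 64), jitter = 0, seed = 0)
#' positions(lay)
#' @export
generateFibreLayout <- function(nFibres, gridShape, jitter = 0.3, seed = 0L) {
  stopifnot(nFibres >= 1, length(gridShape) == 2, all(gridShape >= 2),
            jitter >= 0, jitter < 0.5)
  fov <- defaultFov(gridShape)
  cx <- fov$center[1]; cy <- fov$center[2]; R <- fov$radius

  if (nFibres == 1L) {
    return(FibreLayout(matrix(c(cx, cy), 1, 2), fov$center, R))
  }

  hexPoints <- function(a) {
    pad <- jitter * a / 2 * sqrt(2) + 1e-6
    rmax <- R - pad
    if (rmax <= 0) return(NULL)
    jmax <- ceiling(rmax / (a * sqrt(3) / 2))
    imax <- ceiling(rmax / a) + 1L
    j <- seq(-jmax, jmax)
    pts <- do.call(rbind, lapply(j, function(jj) {
      i <- seq(-imax, imax)
      cbind(cx + (i + (jj %% 2) / 2) * a, cy + jj * a * sqrt(3) / 2)
    }))
    d2 <- (pts[, 1] - cx)^2 + (pts[, 2] - cy)^2
    pts[d2 <= rmax^2, , drop = FALSE]
  }

  # start from the ideal hex pitch for the target density, shrink until the
  # disc holds enough lattice sites; sub-pixel pitches are unphysical
  a <- sqrt(2 * pi * R^2 / (sqrt(3) * nFibres)) * 0.98
  if (a < 1.0)
    stop("requested nFibres (", nFibres,
         ") exceeds the lattice capacity inside the field of view")
  pts <- hexPoints(a)
  while ((is.null(pts) || nrow(pts) < nFibres) && a > 1.0) {
    a <- a * 0.97
    pts <- hexPoints(a)
  }
  if (is.null(pts) || nrow(pts) < nFibres)
    stop("requested nFibres (", nFibres,
         ") exceeds the lattice capacity inside the field of view")

  # deterministic compact fill: closest sites first (distance, then angle)
  d2 <- (pts[, 1] - cx)^2 + (pts[, 2] - cy)^2
  ang <- atan2(pts[, 2] - cy, pts[, 1] - cx)
  ord <- order(round(d2, 9), round(ang, 12))
  pts <- pts[ord[seq_len(nFibres)], , drop = FALSE]

  if (jitter > 0) {
    pts <- withSeed(seed, {
      pts + matrix(runif(2 * nFibres, -jitter * a / 2, jitter * a / 2),
                   ncol = 2)
    })
  }
  FibreLayout(pts, fov$center, R)
}

#' Compute the Voronoi sampling partition of a pixel grid
#'
#' Labels every pixel inside the field of view with the 0-based index of its
#' nearest fibre (Euclidean distance from pixel centre to fibre centre; ties
#' broken by the lowest fibre index). Pixels outside the FOV disc get the
#' sentinel \code{-1}.
#'
#' @param layout a \linkS4class{FibreLayout}.
#' @param gridShape integer \code{(rows, cols)} of the pixel grid.
#' @return a \linkS4class{VoronoiMap}.
#' @export
computeVoronoiMap <- function(layout, gridShape) {
  stopifnot(is(layout, "FibreLayout"), length(gridShape) == 2,
            all(gridShape >= 1))
  pos <- positions(layout)
  nf <- nrow(pos)
  mask <- fovMask(gridShape, fovCenter(layout), fovRadius(layout))
  pc <- pixelCoords(gridShape)
  px <- pc$x[mask]; py <- pc$y[mask]

  best <- rep.int(1L, length(px))
  bestD2 <- (px - pos[1, 1])^2 + (py - pos[1, 2])^2
  if (nf > 1L) for (j in 2:nf) {
    d2 <- (px - pos[j, 1])^2 + (py - pos[j, 2])^2
    upd <- d2 < bestD2          # strict: ties keep the lower index
    if (any(upd)) {
      best[upd] <- j
      bestD2[upd] <- d2[upd]
    }
  }
  labels <- matrix(-1L, gridShape[1], gridShape[2])
  labels[mask] <- best - 1L
  new("VoronoiMap", labels = labels,
      cellSizes = tabulate(best, nbins = nf))
}

#' Extract per-fibre signals from a high-resolution frame
#'
#' Simulates the fibre acquisition point spread: each fibre's signal is the
#' arithmetic mean of the HR pixel values inside that fibre's Voronoi cell.
#' Fibres whose cell contains no pixel of the grid are flagged missing
#' (\code{NA}).
#'
#' @param hr an \linkS4class{ImageFrame} (or matrix), same shape as
#'   \code{vmap}.
#' @param vmap a \linkS4class{VoronoiMap} for the same grid.
#' @return an unnormalized, unpadded \linkS4class{FibreSignalVector}.
#' @export
extractFibreSignals <- function(hr, vmap) {
  img <- .fd(hr)
  lab <- cellLabels(vmap)
  if (!all(dim(img) == dim(lab)))
    stop("image shape ", paste(dim(img), collapse = "x"),
         " does not match Voronoi map shape ", paste(dim(lab), collapse = "x"))
  nf <- nFibres(vmap)
  inside <- lab >= 0L
  byCell <- split(img[inside], factor(lab[inside] + 1L, levels = seq_len(nf)))
  means <- vapply(byCell, function(v) if (length(v)) mean(v) else NA_real_, 0)
  FibreSignalVector(unname(means), normalized = FALSE)
}

#' Corrupt fibre signals with additive and multiplicative Gaussian noise
#'
#' Applies \code{nfs = fs * (1 + m) + a} with independent zero-mean Gaussians
#' per fibre (see [noiseParams()]); negative results are clipped to zero. With
#' both standard deviations zero the input is returned unchanged.
#'
#' @param signals a raw \linkS4class{FibreSignalVector}.
#' @param params a \code{NoiseParams} list from [noiseParams()].
#' @return a \linkS4class{FibreSignalVector} of noisy signals.
#' @export
addFibreNoise <- function(signals, params) {
  stopifnot(is(signals, "FibreSignalVector"), inherits(params, "NoiseParams"))
  if (params$sigmaAdd == 0 && params$sigmaMult == 0) return(signals)
  n <- nFibres(signals)
  fs <- signalValues(signals)[seq_len(n)]
  nfs <- withSeed(params$seed, {
    m <- rnorm(n, 0, params$sigmaMult)
    a <- rnorm(n, 0, params$sigmaAdd)
    fs * (1 + m) + a
  })
  nfs <- pmax(nfs, 0)
  FibreSignalVector(nfs, paddedLength = paddedLength(signals),
                    normalized = FALSE, fibreIds = fibreIds(signals))
}

#' Reconstruct a low-resolution frame from fibre signals
#'
#' Delaunay-based linear reconstruction: pixel values inside the convex hull
#' of the fibre centres are barycentric-linear interpolations of the signals
#' at the vertices of the enclosing Delaunay triangle. Pixels inside the field
#' of view but outside the hull take the nearest fibre's signal (zeroth-order
#' extrapolation); pixels outside the FOV are zero. Missing signals (fibres
#' with empty Voronoi cells) are imputed as the mean of their
#' Delaunay-adjacent fibres before interpolation.
#'
#' @param signals a \linkS4class{FibreSignalVector} with one real entry per
#'   fibre of \code{layout}.
#' @param layout the \linkS4class{FibreLayout} (needs >= 3 non-collinear
#'   fibres).
#' @param gridShape integer \code{(rows, cols)} of the output grid.
#' @return an \linkS4class{ImageFrame} with role \code{"LR"}.
#' @export
reconstructLR <- function(signals, layout, gridShape) {
  stopifnot(is(signals, "FibreSignalVector"), is(layout, "FibreLayout"))
  pos <- positions(layout)
  nf <- nrow(pos)
  if (nFibres(signals) != nf)
    stop("signal count (", nFibres(signals),
         ") does not match layout fibre count (", nf, ")")
  if (nf < 3L) stop("Delaunay reconstruction needs at least 3 fibres")
  vals <- signalValues(signals)[seq_len(nf)]

  tri <- delaunayTriangulate(pos)

  if (anyNA(vals)) {
    adj <- .delaunayNeighbours(tri, nf)
    miss <- which(is.na(vals))
    for (i in miss) {
      nb <- vals[adj[[i]]]
      vals[i] <- if (all(is.na(nb))) mean(vals, na.rm = TRUE)
                 else mean(nb, na.rm = TRUE)
    }
  }

  px <- .rasterizeTriangulation(tri, pos, vals, gridShape)
  mask <- fovMask(gridShape, fovCenter(layout), fovRadius(layout))
  hole <- is.na(px) & as.vector(mask)
  if (any(hole)) {
    pc <- pixelCoords(gridShape)
    hx <- pc$x[hole]; hy <- pc$y[hole]
    best <- rep.int(1L, length(hx))
    bestD2 <- (hx - pos[1, 1])^2 + (hy - pos[1, 2])^2
    if (nf > 1L) for (j in 2:nf) {
      d2 <- (hx - pos[j, 1])^2 + (hy - pos[j, 2])^2
      upd <- d2 < bestD2
      best[upd] <- j
      bestD2[upd] <- d2[upd]
    }
    px[hole] <- vals[best]
  }
  px[!mask] <- 0
  px[is.na(px)] <- 0
  ImageFrame(matrix(px, gridShape[1], gridShape[2]), role = "LR")
}

#' Simulate a low-resolution pCLE frame from a high-resolution frame
#'
#' The full physics-based acquisition chain: Voronoi-cell averaging of the HR
#' frame into per-fibre signals, additive/multiplicative Gaussian signal
#' noise, and Delaunay-based linear reconstruction back to the pixel grid.
#' The returned signal vector is exactly the acquisition vector
#' \code{V(I_LR)} of the simulated frame.
#'
#' @param hr an \linkS4class{ImageFrame} (or matrix).
#' @param layout a \linkS4class{FibreLayout}.
#' @param params a \code{NoiseParams} list; see [noiseParams()].
#' @param vmap optional precomputed \linkS4class{VoronoiMap} for the grid of
#'   \code{hr} (computed when missing).
#' @return a list with elements \code{lr} (\linkS4class{ImageFrame}),
#'   \code{signals} (the noisy acquisition \linkS4class{FibreSignalVector})
#'   and \code{vmap}.
#' @examples
#' lay <- generateFibreLayout(40, c(48, 48), jitter = 0.3, seed = 1)
#' hr <- ImageFrame(matrix(runif(48 * 48), 48, 48), role = "HR")
#' sim <- simulateLRfromHR(hr, lay, noiseParams(0.01, 0.02, seed = 1))
#' sim$lr
#' @export
simulateLRfromHR <- function(hr, layout, params = noiseParams(),
                             vmap = NULL) {
  img <- .fd(hr)
  if (is.null(vmap)) vmap <- computeVoronoiMap(layout, dim(img))
  fs <- extractFibreSignals(img, vmap)
  nfs <- addFibreNoise(fs, params)
  lr <- reconstructLR(nfs, layout, dim(img))
  list(lr = lr, signals = nfs, vmap = vmap)
}
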