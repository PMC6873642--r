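# Synthetic study generation: tissue-like HR textures, natural-texture
# stand-ins, and full paired/unpaired HR-LR studies with video/patient
# grouping metadata. Everything is generated in code; no downloads.

# Periodic Gaussian smoothing via FFT; kernel normalized to sum 1, so
# smoothing white noise shrinks its standard deviation roughly by
# 1 / (corrLength * sqrt(4 * pi)) — long correlation lengths flatten the
# field instead of being re-amplified.
.fftSmooth <- function(m, sigma) {
  n1 <- nrow(m); n2 <- ncol(m)
  d1 <- pmin(0:(n1 - 1), n1 - 0:(n1 - 1))
  d2 <- pmin(0:(n2 - 1), n2 - 0:(n2 - 1))
  k <- exp(-outer(d1^2, d2^2, `+`) / (2 * sigma^2))
  k <- k / sum(k)
  Re(fft(fft(m) * fft(k), inverse = TRUE)) / (n1 * n2)
}

#' Synthetic study specification
#'
#' Describes a synthetic pCLE study: cohort structure (patients, videos per
#' patient, frames per video), frame and bundle geometry, texture parameters
#' of the tissue stand-in, the fibre noise model, and the misalignment bounds
#' used by the unpaired variant.
#'
#' @param nPatients,videosPerPatient,framesPerVideo cohort structure counts.
#' @param frameSize frame side in pixels.
#' @param nFibres fibres in the bundle.
#' @param textureParams list with \code{corrLength} (pixels),
#'   \code{blobDensity} (expected cell blobs per 64x64 tile) and
#'   \code{contrast} (blob amplitude in intensity units).
#' @param noise a [noiseParams()] list (its seed is re-derived per frame).
#' @param misalignment list with \code{maxShift} (pixels) and
#'   \code{maxRotation} (degrees); used only in unpaired mode.
#' @param seed master seed; all per-frame seeds derive from it.
#' @return a validated \code{SyntheticStudySpec} list.
#' @export
syntheticStudySpec <- function(nPatients = 4L, videosPerPatient = 2L,
                               framesPerVideo = 3L, frameSize = 128L,
                               nFibres = 200L,
                               textureParams = list(corrLength = 6,
                                                    blobDensity = 6,
                                                    contrast = 0.6),
                               noise = noiseParams(),
                               misalignment = list(maxShift = 3,
                                                   maxRotation = 3),
                               seed = 0L) {
  stopifnot(nPatients >= 1, videosPerPatient >= 1, framesPerVideo >= 1,
            frameSize >= 64, nFibres >= 3,
            all(c("corrLength", "blobDensity", "contrast") %in%
                  names(textureParams)),
            inherits(noise, "NoiseParams"),
            all(c("maxShift", "maxRotation") %in% names(misalignment)))
  structure(list(nPatients = as.integer(nPatients),
                 videosPerPatient = as.integer(videosPerPatient),
                 framesPerVideo = as.integer(framesPerVideo),
                 frameSize = as.integer(frameSize),
                 nFibres = as.integer(nFibres),
                 textureParams = textureParams, noise = noise,
                 misalignment = misalignment, seed = as.integer(seed)),
            class = "SyntheticStudySpec")
}

#' Generate a tissue-like high-resolution texture
#'
#' Stand-in for an estimated HR tissue frame: a smoothed Gaussian random
#' field (correlation length in pixels) plus bright elliptical "cell" blobs
#' at the stated density, clipped to \code{[0, 1]}. Longer correlation
#' lengths flatten the background field; zero blob density gives pure
#' background.
#'
#' @param size frame side in pixels.
#' @param textureParams list with \code{corrLength}, \code{blobDensity},
#'   \code{contrast}; see [syntheticStudySpec()].
#' @param seed integer seed; identical seeds give identical frames.
#' @return an \linkS4class{ImageFrame} with role \code{"HR"}.
#' @export
generateTextureHR <- function(size = 128L,
                              textureParams = list(corrLength = 6,
                                                   blobDensity = 6,
                                                   contrast = 0.6),
                              seed = 0L) {
  stopifnot(size >= 64)
  cl <- textureParams$corrLength
  dens <- textureParams$blobDensity
  amp <- textureParams$contrast
  img <- withSeed(seed, {
    noise <- matrix(rnorm(size * size, 0, 0.25 * 8 * sqrt(4 * pi)),
                    size, size)
    base <- 0.45 + .fftSmooth(noise, cl)
    nBlobs <- round(dens * (size / 64)^2)
    if (nBlobs > 0) for (k in seq_len(nBlobs)) {
      bx <- runif(1, 0, size); by <- runif(1, 0, size)
      a <- runif(1, 3, 9); b <- runif(1, 3, 9)
      th <- runif(1, 0, pi)
      A <- amp * runif(1, 0.6, 1)
      ext <- 3 * max(a, b)
      c0 <- max(1L, floor(bx - ext)); c1 <- min(size, ceiling(bx + ext))
      r0 <- max(1L, floor(by - ext)); r1 <- min(size, ceiling(by + ext))
      if (c0 > c1 || r0 > r1) next
      xs <- (c0:c1) - 0.5 - bx
      ys <- (r0:r1) - 0.5 - by
      # rotated local coordinates (rows = y, cols = x)
      X <- matrix(rep(xs, each = length(ys)), length(ys))
      Y <- matrix(rep(ys, times = length(xs)), length(ys))
      U <- X * cos(th) + Y * sin(th)
      V <- -X * sin(th) + Y * cos(th)
      q <- (U / a)^2 + (V / b)^2
      base[r0:r1, c0:c1] <- base[r0:r1, c0:c1] + A * exp(-q / 2)
    }
    base
  })
  ImageFrame(clamp(img, 0, 1), role = "HR")
}

#' Generate natural-image stand-in patches
#'
#' Synthetic substitute for grayscale natural-image target patches: composites
#' of multi-octave noise and sharp oriented step edges, which carry markedly
#' more high-frequency energy than the tissue textures of
#' [generateTextureHR()]. A directory of real grayscale images can be used
#' instead via [readImageFrame()] + [buildTargetDomain()].
#'
#' @param nPatches number of patches.
#' @param patchSize patch side in pixels.
#' @param seed integer seed.
#' @return list of \linkS4class{ImageFrame}s with values in \code{[0, 1]}.
#' @export
generateNaturalStandin <- function(nPatches, patchSize = 64L, seed = 0L) {
  stopifnot(nPatches >= 1, patchSize >= 8)
  withSeed(seed, {
    lapply(seq_len(nPatches), function(k) {
      f <- matrix(0, patchSize, patchSize)
      # octaves: white to coarse, flat-ish spectrum keeps high frequencies
      for (o in 0:3) {
        sigma <- 2^o / 2
        f <- f + .fftSmooth(matrix(rnorm(patchSize^2), patchSize), sigma) *
          (1.5^o)
      }
      f <- (f - mean(f)) / max(sd(f), 1e-12) * 0.18 + 0.5
      # oriented step edges
      nEdges <- sample(1:3, 1)
      xs <- seq_len(patchSize) - 0.5
      X <- matrix(rep(xs, each = patchSize), patchSize)
      Y <- matrix(rep(xs, times = patchSize), patchSize)
      for (e in seq_len(nEdges)) {
        th <- runif(1, 0, pi)
        off <- runif(1, 0.25, 0.75) * patchSize
        d <- X * cos(th) + Y * sin(th) - off
        f <- f + runif(1, -0.25, 0.25) * tanh(d / 0.75)
      }
      ImageFrame(clamp(f, 0, 1), role = "HR")
    })
  })
}

# Rigid transform (shift + rotation about the frame centre) with bilinear
# resampling and replicated borders; models video-registration misalignment.
.rigidTransform <- function(m, dx, dy, thetaDeg) {
  H <- nrow(m); W <- ncol(m)
  th <- thetaDeg * pi / 180
  cx <- W / 2; cy <- H / 2
  xs <- seq_len(W) - 0.5
  ys <- seq_len(H) - 0.5
  X <- matrix(rep(xs, each = H), H)
  Y <- matrix(rep(ys, times = W), H)
  # inverse map: rotate by -theta about centre, then unshift
  Xc <- X - cx - dx; Yc <- Y - cy - dy
  Xs <- Xc * cos(th) + Yc * sin(th) + cx
  Ys <- -Xc * sin(th) + Yc * cos(th) + cy
  cs <- clamp(Xs + 0.5, 1, W); rs <- clamp(Ys + 0.5, 1, H)
  c0 <- pmin(floor(cs), W - 1); r0 <- pmin(floor(rs), H - 1)
  fc <- cs - c0; fr <- rs - r0
  i00 <- (c0 - 1) * H + r0
  v <- (1 - fr) * (1 - fc) * m[i00] + fr * (1 - fc) * m[i00 + 1] +
       (1 - fr) * fc * m[i00 + H] + fr * fc * m[i00 + H + 1]
  matrix(v, H, W)
}

#' Generate a full synthetic study
#'
#' Builds an HR/LR study emulating the two database variants used for
#' training: in \code{paired} mode each LR frame is simulated from its HR
#' frame through the acquisition chain ([simulateLRfromHR()]) with perfect
#' alignment and a stored acquisition vector; in \code{unpaired} mode the LR
#' is simulated from a rigidly misaligned copy of the HR (random shift and
#' rotation within the spec bounds), emulating HR references estimated by
#' video registration. Grouping metadata (frame, video, patient, clinical
#' setting — two settings assigned per patient) is produced alongside for
#' CS1/CS2 splits.
#'
#' @param spec a [syntheticStudySpec()].
#' @param mode \code{"paired"} or \code{"unpaired"}.
#' @return a \code{fibreStudy} list: named lists \code{hr}, \code{lr},
#'   \code{signals}; \code{metadata} data.frame (\code{frame_id},
#'   \code{video_id}, \code{patient_id}, \code{clinical_setting});
#'   \code{layout}; \code{vmap}; \code{spec}; \code{mode}.
#' @export
generateStudy <- function(spec = syntheticStudySpec(),
                          mode = c("paired", "unpaired")) {
  mode <- match.arg(mode)
  gs <- c(spec$frameSize, spec$frameSize)
  layout <- generateFibreLayout(spec$nFibres, gs, jitter = 0.3,
                                seed = spec$seed + 1000L)
  vmap <- computeVoronoiMap(layout, gs)

  hr <- list(); lr <- list(); signals <- list()
  meta <- list()
  idx <- 0L
  for (p in seq_len(spec$nPatients)) {
    setting <- if (p %% 2L == 1L) "colon" else "oesophagus"
    for (v in seq_len(spec$videosPerPatient)) {
      for (f in seq_len(spec$framesPerVideo)) {
        idx <- idx + 1L
        fid <- sprintf("P%02dV%02dF%03d", p, v, f)
        fseed <- spec$seed + 7919L * idx
        hrF <- generateTextureHR(spec$frameSize, spec$textureParams,
                                 seed = fseed)
        src <- hrF
        if (mode == "unpaired") {
          mis <- withSeed(fseed + 1L, {
            c(runif(2, -spec$misalignment$maxShift,
                    spec$misalignment$maxShift),
              runif(1, -spec$misalignment$maxRotation,
                    spec$misalignment$maxRotation))
          })
          src <- ImageFrame(.rigidTransform(frameData(hrF), mis[1], mis[2],
                                            mis[3]), role = "HR")
        }
        np <- noiseParams(spec$noise$sigmaAdd, spec$noise$sigmaMult,
                          seed = fseed + 2L)
        sim <- simulateLRfromHR(src, layout, np, vmap = vmap)
        hr[[fid]] <- hrF
        lr[[fid]] <- sim$lr
        signals[[fid]] <- sim$signals
        meta[[idx]] <- data.frame(frame_id = fid,
                                  video_id = sprintf("P%02dV%02d", p, v),
                                  patient_id = sprintf("P%02d", p),
                                  clinical_setting = setting,
                                  stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(hr = hr, lr = lr, signals = signals,
                 metadata = do.call(rbind, meta),
                 layout = layout, vmap = vmap, spec = spec, mode = mode),
            class = "fibreStudy")
}

#' Assemble training samples from a paired study
#'
#' Crops each frame to the square inscribed in the field of view, tiles that
#' square with non-overlapping patches (all guaranteed FOV-interior), and
#' bundles each LR patch with its Voronoi map window and its normalized
#' acquisition vector (raw-signal path), padded to a common \code{N_F} (the
#' maximum fibre count over all patches). Aligned HR patches are attached for
#' validation monitoring.
#'
#' @param study a \code{fibreStudy} from [generateStudy()].
#' @param patchSize training patch side in pixels.
#' @param frameIds frames to use (default: all).
#' @return list with \code{samples} (list of [trainingSample()]s) and
#'   \code{NF}.
#' @export
studyTrainingSamples <- function(study, patchSize = 32L,
                                 frameIds = names(study$lr)) {
  ctr <- fovCenter(study$layout)
  side <- floor(fovRadius(study$layout) * sqrt(2))
  nt <- side %/% patchSize
  if (nt < 1L) stop("patchSize exceeds the FOV-inscribed square")
  r0 <- round(ctr[2] - side / 2); c0 <- round(ctr[1] - side / 2)
  offs <- expand.grid(r = r0 + (seq_len(nt) - 1L) * patchSize,
                      c = c0 + (seq_len(nt) - 1L) * patchSize)
  pieces <- list()
  for (fid in frameIds) {
    lrM <- .fd(study$lr[[fid]]); hrM <- .fd(study$hr[[fid]])
    for (i in seq_len(nrow(offs))) {
      rr <- offs$r[i] + seq_len(patchSize)
      cc <- offs$c[i] + seq_len(patchSize)
      vm <- cropVoronoiMap(study$vmap, offs$r[i], offs$c[i], patchSize)
      pieces[[length(pieces) + 1L]] <-
        list(lr = lrM[rr, cc], hr = hrM[rr, cc], vmap = vm,
             raw = study$signals[[fid]], nVis = sum(cellSizes(vm) > 0L))
    }
  }
  if (!length(pieces)) stop("no patches fall inside the field of view")
  NF <- max(vapply(pieces, function(p) p$nVis, 0L))
  samples <- lapply(pieces, function(p)
    trainingSample(p$lr, p$vmap,
                   acquisitionVector(vmap = p$vmap, rawSignals = p$raw,
                                     paddedLen = NF),
                   hr = p$hr))
  list(samples = samples, NF = NF)
}
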