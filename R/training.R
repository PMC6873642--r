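#' Training configuration
#'
#' Hyperparameters of the adversarial run. The optimizer defaults follow the
#' original training protocol (Adam with beta1 = 0.9, beta2 = 0.999,
#' eps = 1e-8, learning rate 1e-4, mini-batches of 54 patches; convergence at
#' full scale takes 50-80 thousand iterations). \code{maxIterations} defaults
#' to a desk-scale 2000; see the vignette for the desk-scale protocol used in
#' the test-suite experiments.
#'
#' @param batchSize patches per mini-batch.
#' @param learningRate Adam learning rate (both networks).
#' @param adamBeta1,adamBeta2,adamEps Adam moment/stability constants.
#' @param maxIterations number of alternating update iterations.
#' @param patchSize training patch side in pixels.
#' @param seed integer seed governing every stochastic element of the run.
#' @param lossWeights numeric length-3 \code{(w_vec, w_adv, w_reg)}.
#' @param targetDomain one of \code{"nat"}, \code{"orig"}, \code{"syn"},
#'   \code{"res"} (recorded in the run log; the caller assembles the pool
#'   with [buildTargetDomain()]).
#' @param validateEvery iterations between validation evaluations.
#' @return a validated \code{TrainingConfig} list.
#' @export
trainingConfig <- function(batchSize = 54L, learningRate = 1e-4,
                           adamBeta1 = 0.9, adamBeta2 = 0.999,
                           adamEps = 1e-8, maxIterations = 2000L,
                           patchSize = 64L, seed = 0L,
                           lossWeights = c(1, 1, 1),
                           targetDomain = c("nat", "orig", "syn", "res"),
                           validateEvery = 50L) {
  targetDomain <- match.arg(targetDomain)
  stopifnot(batchSize >= 1, learningRate > 0, adamBeta1 > 0, adamBeta2 > 0,
            adamEps > 0, maxIterations >= 0, patchSize >= 1,
            length(lossWeights) == 3, all(lossWeights >= 0),
            validateEvery >= 1)
  structure(list(batchSize = as.integer(batchSize),
                 learningRate = learningRate, adamBeta1 = adamBeta1,
                 adamBeta2 = adamBeta2, adamEps = adamEps,
                 maxIterations = as.integer(maxIterations),
                 patchSize = as.integer(patchSize), seed = as.integer(seed),
                 lossWeights = as.numeric(lossWeights),
                 targetDomain = targetDomain,
                 validateEvery = as.integer(validateEvery)),
            class = "TrainingConfig")
}

#' Bundle a training sample
#'
#' One unsupervised training sample: an LR patch, the Voronoi map of its
#' window, and its normalized acquisition vector. An aligned HR patch may be
#' attached for validation monitoring only (the loss never sees it).
#'
#' @param lr LR patch (matrix or \linkS4class{ImageFrame}).
#' @param vmap patch \linkS4class{VoronoiMap} (see [cropVoronoiMap()]).
#' @param vLr normalized, padded acquisition \linkS4class{FibreSignalVector}.
#' @param hr optional aligned HR patch for monitoring.
#' @return a \code{trainingSample} list.
#' @export
trainingSample <- function(lr, vmap, vLr, hr = NULL) {
  stopifnot(is(vmap, "VoronoiMap"), is(vLr, "FibreSignalVector"),
            isNormalized(vLr))
  structure(list(lr = .fd(lr), vmap = vmap, vLr = vLr,
                 hr = if (!is.null(hr)) .fd(hr)),
            class = "trainingSample")
}

# Per-sample cycle geometry cached for the training loop: pixel indices per
# visible cell and the target normalized vector.
.cycleInfo <- function(sample) {
  lab <- cellLabels(sample$vmap)
  counts <- cellSizes(sample$vmap)
  present <- which(counts > 0L)
  pix <- split(which(lab >= 0L), lab[lab >= 0L] + 1L)  # named by cell index
  list(present = present,
       pix = pix[as.character(present)],
       counts = counts[present],
       target = signalValues(sample$vLr),
       nReal = length(present))
}

# l_vec value and gradient w.r.t. the SR patch pixels for one sample. The
# min-max normalization statistics are treated as constants during
# backpropagation (a stop-gradient; see the vignette's numerical notes).
.lvecAndGrad <- function(sr, info, NF) {
  m <- vapply(info$pix, function(ix) mean(sr[ix]), 0)
  mn <- min(m); mx <- max(m)
  vhat <- numeric(NF)
  grad <- matrix(0, nrow(sr), ncol(sr))
  if (mx > mn) {
    vn <- (m - mn) / (mx - mn)
    vhat[seq_len(info$nReal)] <- vn
    diff <- vhat - info$target
    dM <- 2 * diff[seq_len(info$nReal)] / (NF * (mx - mn))
    for (j in seq_len(info$nReal))
      grad[info$pix[[j]]] <- grad[info$pix[[j]]] + dM[j] / info$counts[j]
  }
  list(value = mean((vhat - info$target)^2), grad = grad)
}

# l_reg value and gradient w.r.t. the SR patch.
.lregAndGrad <- function(lr, sr) {
  H <- nrow(sr); W <- ncol(sr)
  rd <- rowMeans(sr) - rowMeans(lr)
  cd <- colMeans(sr) - colMeans(lr)
  g <- matrix(rd * (2 / (H * W)), H, W) +
       matrix(cd * (2 / (H * W)), H, W, byrow = TRUE)
  list(value = mean(rd^2) + mean(cd^2), grad = g)
}

#' Adversarial training with cycle consistency
#'
#' Concurrent training of the super-resolution generator and the
#' discriminator on unpaired pools: each iteration performs one discriminator
#' update (gradient ascent on its objective, implemented as cross-entropy
#' descent) followed by one generator update (descent on the composite loss:
#' cycle-consistency + non-saturating adversarial + row/column-mean
#' regularizer), both with Adam. White noise on the discriminator inputs
#' decays linearly to zero over the run. Validation losses (and, when HR
#' monitoring patches are attached, the composite quality score) are logged
#' every \code{validateEvery} iterations, and the generator checkpoint with
#' the lowest validation total loss is returned.
#'
#' @param samples list of [trainingSample()]s (the unpaired LR pool), all
#'   padded to the same \code{N_F}.
#' @param targets list of target-domain patches (matrices or
#'   \linkS4class{ImageFrame}s) of the training patch size.
#' @param config a [trainingConfig()].
#' @param genSpec,discSpec network specifications; see [generatorSpec()] and
#'   [discriminatorSpec()].
#' @param valSamples optional list of [trainingSample()]s held out for
#'   validation.
#' @return list with \code{generator} (checkpoint with the best validation
#'   total loss, or the final/initial generator when no validation samples are
#'   given), \code{log} (per-iteration losses), \code{valLog} (validation
#'   trace) and \code{config}.
#' @export
trainAdversarial <- function(samples, targets, config = trainingConfig(),
                             genSpec = generatorSpec(),
                             discSpec = discriminatorSpec(),
                             valSamples = list()) {
  stopifnot(length(samples) >= 1, length(targets) >= 1)
  H <- nrow(samples[[1]]$lr); W <- ncol(samples[[1]]$lr)
  NF <- paddedLength(samples[[1]]$vLr)
  for (s in samples) {
    stopifnot(nrow(s$lr) == H, ncol(s$lr) == W)
    if (paddedLength(s$vLr) != NF)
      stop("all acquisition vectors must share the same padded length N_F")
  }
  infos <- lapply(samples, .cycleInfo)
  valInfos <- lapply(valSamples, .cycleInfo)
  targetMats <- lapply(targets, .fd)
  w <- config$lossWeights

  gen <- buildGenerator(genSpec, seed = config$seed)
  disc <- buildDiscriminator(discSpec, inputShape = c(H, W),
                             seed = config$seed + 1L)

  log <- data.frame(iter = integer(), l_vec = double(), l_adv = double(),
                    l_reg = double(), total = double(),
                    d_objective = double())
  valLog <- data.frame(iter = integer(), l_vec = double(), l_adv = double(),
                       l_reg = double(), total = double(), tot_cs = double())

  if (config$maxIterations == 0L)
    return(list(generator = gen, log = log, valLog = valLog, config = config))

  validate <- function(iter) {
    if (!length(valSamples)) return(NULL)
    lv <- la <- lrg <- tc <- numeric(length(valSamples))
    for (i in seq_along(valSamples)) {
      s <- valSamples[[i]]
      sr <- .genForward(gen, matrix(as.vector(s$lr), ncol = 1L), H, W, 1L)$out
      srM <- matrix(sr, H, W)
      lv[i] <- .lvecAndGrad(srM, valInfos[[i]], NF)$value
      lrg[i] <- .lregAndGrad(s$lr, srM)$value
      la[i] <- lossAdv(.discForward(disc, sr, 1L, train = FALSE)$prob)
      tc[i] <- if (!is.null(s$hr) && nrow(srM) >= 11L)
        totCS(metricSSIM(clamp(srM, 0, 1), s$hr),
              metricGCF(clamp(srM, 0, 1)) - metricGCF(s$hr))
      else NA_real_
    }
    data.frame(iter = iter, l_vec = mean(lv), l_adv = mean(la),
               l_reg = mean(lrg),
               total = sum(w * c(mean(lv), mean(la), mean(lrg))),
               tot_cs = mean(tc))
  }

  bestVal <- Inf
  bestParams <- gen$params

  withSeed(config$seed, {
    genState <- adamInit(gen$params)
    discState <- adamInit(disc$params)
    v0 <- validate(0L)
    if (!is.null(v0)) {
      valLog <- rbind(valLog, v0)
      bestVal <- v0$total
    }

    for (t in seq_len(config$maxIterations)) {
      sigmaT <- discSpec$inputNoiseSigma *
        (1 - (t - 1) / max(1L, config$maxIterations))
      idxS <- sample.int(length(samples), config$batchSize, replace = TRUE)
      idxT <- sample.int(length(targetMats), config$batchSize, replace = TRUE)
      B <- config$batchSize

      Xlr <- .stackPatches(lapply(idxS, function(i) samples[[i]]$lr))
      gfwd <- .genForward(gen, Xlr, H, W, B)
      SR <- gfwd$out

      # -- discriminator step (ascend its objective) --
      Xt <- .stackPatches(targetMats[idxT])
      fr <- .discForward(disc, Xt, B, train = TRUE, noiseSigma = sigmaT)
      ff <- .discForward(disc, SR, B, train = TRUE, noiseSigma = sigmaT)
      dr <- clamp(fr$prob, 1e-7, 1 - 1e-7)
      df <- clamp(ff$prob, 1e-7, 1 - 1e-7)
      dObj <- mean(log(1 - df)) + mean(log(dr))
      gR <- .discBackward(disc, fr$cache, 1 / (B * dr))
      gF <- .discBackward(disc, ff$cache, -1 / (B * (1 - df)))
      dGrads <- Map(`+`, gR$grads, gF$grads)
      upd <- adamStep(disc$params, dGrads, discState,
                      lr = config$learningRate, beta1 = config$adamBeta1,
                      beta2 = config$adamBeta2, eps = config$adamEps,
                      direction = +1)
      disc$params <- upd$params; discState <- upd$state

      # -- generator step (descend the composite loss) --
      f2 <- .discForward(disc, SR, B, train = TRUE, noiseSigma = sigmaT)
      df2 <- clamp(f2$prob, 1e-7, 1)
      lAdv <- mean(-log(df2))
      bAdv <- .discBackward(disc, f2$cache, -1 / (B * df2))
      dSR <- w[2] * bAdv$dX

      srList <- .unstackPatches(SR, H, W, B)
      lVec <- 0; lReg <- 0
      for (bi in seq_len(B)) {
        s <- samples[[idxS[bi]]]
        vres <- .lvecAndGrad(srList[[bi]], infos[[idxS[bi]]], NF)
        rres <- .lregAndGrad(s$lr, srList[[bi]])
        lVec <- lVec + vres$value / B
        lReg <- lReg + rres$value / B
        rows <- ((bi - 1L) * H * W + 1L):(bi * H * W)
        dSR[rows, 1L] <- dSR[rows, 1L] +
          as.vector(w[1] * vres$grad + w[3] * rres$grad) / B
      }
      total <- sum(w * c(lVec, lAdv, lReg))
      if (!is.finite(total) || !is.finite(dObj))
        stop("training diverged at iteration ", t,
             ": non-finite loss (total = ", total, ", d_obj = ", dObj, ")")

      gback <- .genBackward(gen, gfwd$cache, dSR)
      upd <- adamStep(gen$params, gback$grads, genState,
                      lr = config$learningRate, beta1 = config$adamBeta1,
                      beta2 = config$adamBeta2, eps = config$adamEps,
                      direction = -1)
      gen$params <- upd$params; genState <- upd$state

      log <- rbind(log, data.frame(iter = t, l_vec = lVec, l_adv = lAdv,
                                   l_reg = lReg, total = total,
                                   d_objective = dObj))

      if (t %% config$validateEvery == 0L || t == config$maxIterations) {
        v <- validate(t)
        if (!is.null(v)) {
          valLog <- rbind(valLog, v)
          if (v$total < bestVal) {
            bestVal <- v$total
            bestParams <- gen$params
          }
        }
      }
    }
  })

  if (length(valSamples)) gen$params <- bestParams
  list(generator = gen, log = log, valLog = valLog, config = config)
}
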