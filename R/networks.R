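#' Generator architecture specification
#'
#' A fully convolutional residual network in the style of the SRGAN
#' generator, minus its pixel-shuffle upsampling stages: pCLE frames are
#' already oversampled on the pixel grid, so the output has the same size as
#' the input for any input size. Layout: input 3x3 conv, `nResidualBlocks`
#' residual blocks (conv-activation-conv with skip), a trunk conv with a
#' global feature skip, and an output conv whose result is added to the input
#' frame (global residual). Leaky-ReLU activations; no batch normalization.
#'
#' Paper-scale defaults are 16 blocks of 64 channels; desk-scale experiments
#' use far smaller values (see the package vignette).
#'
#' @param nResidualBlocks number of residual blocks.
#' @param baseChannels feature channels throughout the trunk.
#' @return a validated \code{GeneratorSpec} list.
#' @export
generatorSpec <- function(nResidualBlocks = 16L, baseChannels = 64L) {
  stopifnot(nResidualBlocks >= 1, baseChannels >= 1)
  structure(list(nResidualBlocks = as.integer(nResidualBlocks),
                 baseChannels = as.integer(baseChannels), kernelSize = 3L),
            class = "GeneratorSpec")
}

#' Discriminator architecture specification
#'
#' A strided convolutional stack followed by a dense head producing a single
#' probability that a patch comes from the target domain. Strides alternate
#' 1, 2, 1, 2, ... over the channel sequence. White noise of standard
#' deviation \code{inputNoiseSigma} is added to the inputs in training mode
#' (linearly decayed to zero over a run) to stabilize adversarial training.
#'
#' @param convBlockChannels channel counts of the convolution blocks.
#' @param inputNoiseSigma initial input white-noise standard deviation.
#' @param denseUnits hidden units of the dense head.
#' @return a validated \code{DiscriminatorSpec} list.
#' @export
discriminatorSpec <- function(convBlockChannels = c(64, 64, 128, 128,
                                                    256, 256, 512, 512),
                              inputNoiseSigma = 0.1, denseUnits = 1024L) {
  stopifnot(length(convBlockChannels) >= 1, all(convBlockChannels >= 1),
            inputNoiseSigma >= 0, denseUnits >= 1)
  structure(list(convBlockChannels = as.integer(convBlockChannels),
                 inputNoiseSigma = inputNoiseSigma,
                 denseUnits = as.integer(denseUnits)),
            class = "DiscriminatorSpec")
}

#' Build a super-resolution generator network
#'
#' @param spec a [generatorSpec()].
#' @param seed integer seed for the (He-normal) parameter initialization;
#'   identical seeds give identical initial parameters.
#' @return a generator network handle (list with elements \code{spec} and
#'   \code{params}).
#' @export
buildGenerator <- function(spec = generatorSpec(), seed = 0L) {
  stopifnot(inherits(spec, "GeneratorSpec"))
  Fc <- spec$baseChannels
  params <- withSeed(seed, {
    p <- list()
    p[["in.W"]] <- .heW(9L, Fc);  p[["in.b"]] <- numeric(Fc)
    for (i in seq_len(spec$nResidualBlocks)) {
      p[[paste0("b", i, ".c1.W")]] <- .heW(9L * Fc, Fc)
      p[[paste0("b", i, ".c1.b")]] <- numeric(Fc)
      p[[paste0("b", i, ".c2.W")]] <- .heW(9L * Fc, Fc)
      p[[paste0("b", i, ".c2.b")]] <- numeric(Fc)
    }
    p[["mid.W"]] <- .heW(9L * Fc, Fc); p[["mid.b"]] <- numeric(Fc)
    p[["out.W"]] <- .heW(9L * Fc, 1L); p[["out.b"]] <- numeric(1L)
    p
  })
  structure(list(spec = spec, params = params, ctxCache = new.env()),
            class = "srGenerator")
}

# Forward pass over a batch laid out as (N*H*W) x 1 (see nn-engine.R).
# Returns list(out, cache); cache holds everything the backward pass needs.
.genForward <- function(net, X, H, W, N) {
  p <- net$params
  ctx <- .getConvCtx(net$ctxCache, H, W, N)
  c0 <- .convF(X, p[["in.W"]], p[["in.b"]], ctx)
  a0 <- .lreluF(c0$Y)
  h <- a0
  blocks <- vector("list", net$spec$nResidualBlocks)
  for (i in seq_along(blocks)) {
    f1 <- .convF(h, p[[paste0("b", i, ".c1.W")]],
                 p[[paste0("b", i, ".c1.b")]], ctx)
    t1 <- .lreluF(f1$Y)
    f2 <- .convF(t1, p[[paste0("b", i, ".c2.W")]],
                 p[[paste0("b", i, ".c2.b")]], ctx)
    blocks[[i]] <- list(z1 = f1$Y, Xcol1 = f1$Xcol, Xcol2 = f2$Xcol)
    h <- h + f2$Y
  }
  fm <- .convF(h, p[["mid.W"]], p[["mid.b"]], ctx)
  g <- fm$Y + a0
  fo <- .convF(g, p[["out.W"]], p[["out.b"]], ctx)
  out <- X + fo$Y
  list(out = out,
       cache = list(ctx = ctx, z0 = c0$Y, Xcol0 = c0$Xcol, blocks = blocks,
                    XcolMid = fm$Xcol, XcolOut = fo$Xcol))
}

# Backward pass; dOut has the shape of the output. Returns list(grads, dX).
.genBackward <- function(net, cache, dOut) {
  p <- net$params
  ctx <- cache$ctx
  grads <- list()
  bo <- .convB(dOut, cache$XcolOut, p[["out.W"]], ctx)
  grads[["out.W"]] <- bo$dW; grads[["out.b"]] <- bo$db
  dg <- bo$dX
  bm <- .convB(dg, cache$XcolMid, p[["mid.W"]], ctx)
  grads[["mid.W"]] <- bm$dW; grads[["mid.b"]] <- bm$db
  dh <- bm$dX
  for (i in rev(seq_along(cache$blocks))) {
    bl <- cache$blocks[[i]]
    b2 <- .convB(dh, bl$Xcol2, p[[paste0("b", i, ".c2.W")]], ctx)
    grads[[paste0("b", i, ".c2.W")]] <- b2$dW
    grads[[paste0("b", i, ".c2.b")]] <- b2$db
    dz1 <- .lreluB(b2$dX, bl$z1)
    b1 <- .convB(dz1, bl$Xcol1, p[[paste0("b", i, ".c1.W")]], ctx)
    grads[[paste0("b", i, ".c1.W")]] <- b1$dW
    grads[[paste0("b", i, ".c1.b")]] <- b1$db
    dh <- dh + b1$dX          # residual skip
  }
  da0 <- dh + dg              # trunk + global feature skip
  dz0 <- .lreluB(da0, cache$z0)
  b0 <- .convB(dz0, cache$Xcol0, p[["in.W"]], ctx)
  grads[["in.W"]] <- b0$dW; grads[["in.b"]] <- b0$db
  list(grads = grads, dX = dOut + b0$dX)   # global residual to the input
}

#' Build a discriminator network
#'
#' @param spec a [discriminatorSpec()].
#' @param inputShape \code{(rows, cols)} of the patches the discriminator
#'   will see (the dense head is sized from it).
#' @param seed integer seed for parameter initialization.
#' @return a discriminator network handle.
#' @export
buildDiscriminator <- function(spec = discriminatorSpec(),
                               inputShape = c(64L, 64L), seed = 0L) {
  stopifnot(inherits(spec, "DiscriminatorSpec"), length(inputShape) == 2)
  ch <- spec$convBlockChannels
  strides <- rep(c(1L, 2L), length.out = length(ch))
  h <- inputShape[1]; w <- inputShape[2]
  for (k in seq_along(ch)) if (strides[k] == 2L) {
    h <- ceiling(h / 2); w <- ceiling(w / 2)
  }
  flatDim <- h * w * ch[length(ch)]
  params <- withSeed(seed, {
    p <- list()
    cin <- 1L
    for (k in seq_along(ch)) {
      p[[paste0("c", k, ".W")]] <- .heW(9L * cin, ch[k])
      p[[paste0("c", k, ".b")]] <- numeric(ch[k])
      cin <- ch[k]
    }
    p[["d1.W"]] <- .heW(flatDim, spec$denseUnits)
    p[["d1.b"]] <- numeric(spec$denseUnits)
    p[["d2.W"]] <- matrix(rnorm(spec$denseUnits, 0, sqrt(1 / spec$denseUnits)),
                          spec$denseUnits, 1L)
    p[["d2.b"]] <- numeric(1L)
    p
  })
  structure(list(spec = spec, params = params, strides = strides,
                 inputShape = as.integer(inputShape), ctxCache = new.env()),
            class = "srDiscriminator")
}

# Forward pass. `train = TRUE` adds input white noise (consumes RNG). Returns
# list(prob = N-vector, cache).
.discForward <- function(net, X, N, train = FALSE,
                         noiseSigma = net$spec$inputNoiseSigma) {
  p <- net$params
  if (train && noiseSigma > 0)
    X <- X + rnorm(length(X), 0, noiseSigma)
  h <- net$inputShape[1]; w <- net$inputShape[2]
  convs <- vector("list", length(net$strides))
  A <- X
  for (k in seq_along(net$strides)) {
    ctx <- .getConvCtx(net$ctxCache, h, w, N)
    fc <- .convF(A, p[[paste0("c", k, ".W")]], p[[paste0("c", k, ".b")]],
                 ctx, stride = net$strides[k])
    convs[[k]] <- list(z = fc$Y, Xcol = fc$Xcol, h = h, w = w)
    A <- .lreluF(fc$Y)
    if (net$strides[k] == 2L) { h <- ctx$H2; w <- ctx$W2 }
  }
  Xf <- .flatten(A, h * w, N)
  z1 <- Xf %*% p[["d1.W"]] + rep(p[["d1.b"]], each = N)
  a1 <- .lreluF(z1)
  z2 <- a1 %*% p[["d2.W"]] + p[["d2.b"]]
  prob <- .sigmoid(z2)
  list(prob = as.vector(prob),
       cache = list(convs = convs, Xf = Xf, z1 = z1, a1 = a1,
                    prob = prob, hOut = h, wOut = w, N = N))
}

# Backward pass from d(loss)/d(prob). Returns list(grads, dX) where dX is the
# gradient w.r.t. the (noisy) input batch.
.discBackward <- function(net, cache, dProb) {
  p <- net$params
  N <- cache$N
  grads <- list()
  pr <- cache$prob
  dz2 <- matrix(dProb * pr * (1 - pr), N, 1L)
  grads[["d2.W"]] <- crossprod(cache$a1, dz2)
  grads[["d2.b"]] <- colSums(dz2)
  da1 <- dz2 %*% t(p[["d2.W"]])
  dz1 <- .lreluB(da1, cache$z1)
  grads[["d1.W"]] <- crossprod(cache$Xf, dz1)
  grads[["d1.b"]] <- colSums(dz1)
  dXf <- dz1 %*% t(p[["d1.W"]])
  dA <- .unflatten(dXf, cache$hOut * cache$wOut, N)
  for (k in rev(seq_along(net$strides))) {
    cv <- cache$convs[[k]]
    ctx <- .getConvCtx(net$ctxCache, cv$h, cv$w, N)
    dz <- .lreluB(dA, cv$z)
    bk <- .convB(dz, cv$Xcol, p[[paste0("c", k, ".W")]], ctx,
                 stride = net$strides[k])
    grads[[paste0("c", k, ".W")]] <- bk$dW
    grads[[paste0("c", k, ".b")]] <- bk$db
    dA <- bk$dX
  }
  list(grads = grads, dX = dA)
}

#' Discriminator probabilities for a batch of patches
#'
#' Evaluation-mode forward pass (no input noise): repeated calls on the same
#' input give identical probabilities.
#'
#' @param disc a discriminator from [buildDiscriminator()].
#' @param patches list of patch matrices/\linkS4class{ImageFrame}s matching
#'   the discriminator's input shape.
#' @return numeric vector of probabilities in \code{(0, 1)}.
#' @export
discriminate <- function(disc, patches) {
  stopifnot(inherits(disc, "srDiscriminator"))
  if (!is.list(patches)) patches <- list(patches)
  X <- .stackPatches(patches)
  .discForward(disc, X, length(patches), train = FALSE)$prob
}

#' Super-resolve a frame with a (trained) generator
#'
#' Runs the fully convolutional generator on a frame of any size and clips
#' the result to \code{[0, 1]}. Deterministic: the generator has no stochastic
#' layers at inference.
#'
#' @param generator a generator from [buildGenerator()] or [trainAdversarial()].
#' @param lr input frame (\linkS4class{ImageFrame} or matrix).
#' @return an \linkS4class{ImageFrame} with role \code{"SR"} and the same
#'   spatial shape as the input.
#' @export
inferSR <- function(generator, lr) {
  stopifnot(inherits(generator, "srGenerator"))
  img <- .fd(lr)
  H <- nrow(img); W <- ncol(img)
  out <- .genForward(generator, matrix(as.vector(img), ncol = 1L), H, W, 1L)$out
  ImageFrame(matrix(clamp(out, 0, 1), H, W), role = "SR")
}
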