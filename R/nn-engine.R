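# Minimal convolutional network engine.
#
# There is no deep-learning runtime in this package's dependency set, and the
# networks needed here are small, so the engine is written directly in R: 3x3
# convolutions are evaluated as im2col gathers followed by BLAS matrix
# multiplies, gradients are hand-derived, and optimization is plain Adam.
# Activations for a batch of N single- or multi-channel H x W maps are stored
# as (N*H*W) x C matrices, sample-major, pixels column-major within a sample.

# ---- im2col machinery -------------------------------------------------------

# Gather-index context for 3x3 convolutions on an (H, W) grid with N samples.
# I[p, k] is the row (in the zero-padded activation matrix) of the k-th
# neighbour of pixel-row p; the (N*H*W + 1)-th row is an all-zero pad row.
.makeConvCtx <- function(H, W, N) {
  HW <- H * W
  total <- N * HW
  zeroRow <- total + 1L
  offs <- expand.grid(dr = -1:1, dc = -1:1)   # kernel taps, column-major
  r <- rep(seq_len(H), times = W)
  c <- rep(seq_len(W), each = H)
  I <- matrix(zeroRow, total, 9L)
  sampleOff <- rep((seq_len(N) - 1L) * HW, each = HW)
  for (k in 1:9) {
    rr <- r + offs$dr[k]
    cc <- c + offs$dc[k]
    ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    p <- (cc - 1L) * H + rr
    col1 <- ifelse(ok, p, NA_integer_)
    full <- rep(col1, times = N) + sampleOff
    full[is.na(full)] <- zeroRow
    I[, k] <- full
  }
  # stride-2 row selection (output keeps odd rows/cols)
  rsel <- seq(1L, H, 2L); csel <- seq(1L, W, 2L)
  p2 <- rep((csel - 1L) * H, each = length(rsel)) + rsel
  sel2 <- rep((seq_len(N) - 1L) * HW, each = length(p2)) + p2
  list(I = I, H = H, W = W, N = N, total = total,
       sel2 = sel2, H2 = length(rsel), W2 = length(csel))
}

.getConvCtx <- function(cacheEnv, H, W, N) {
  key <- paste(H, W, N, sep = "x")
  ctx <- cacheEnv[[key]]
  if (is.null(ctx)) {
    ctx <- .makeConvCtx(H, W, N)
    cacheEnv[[key]] <- ctx
  }
  ctx
}

.im2col <- function(X, ctx) {
  C <- ncol(X)
  Xp <- rbind(X, matrix(0, 1L, C))
  out <- matrix(0, ctx$total, 9L * C)
  for (k in 1:9)
    out[, ((k - 1L) * C + 1L):(k * C)] <- Xp[ctx$I[, k], , drop = FALSE]
  out
}

# 3x3 convolution forward. Wm is (9*Cin) x Cout, b length Cout.
.convF <- function(X, Wm, b, ctx, stride = 1L) {
  Xcol <- .im2col(X, ctx)
  if (stride == 2L) Xcol <- Xcol[ctx$sel2, , drop = FALSE]
  Y <- Xcol %*% Wm
  Y <- Y + rep(b, each = nrow(Y))
  list(Y = Y, Xcol = Xcol)
}

# Backward pass; dY matches the (possibly strided) output rows.
.convB <- function(dY, Xcol, Wm, ctx, stride = 1L) {
  Cin <- nrow(Wm) / 9L
  dW <- crossprod(Xcol, dY)
  db <- colSums(dY)
  dXcol <- dY %*% t(Wm)
  rowsSel <- if (stride == 2L) ctx$sel2 else seq_len(ctx$total)
  dX <- matrix(0, ctx$total, Cin)
  for (k in 1:9) {
    tgt <- ctx$I[rowsSel, k]
    ok <- tgt <= ctx$total
    if (!any(ok)) next
    cols <- ((k - 1L) * Cin + 1L):(k * Cin)
    dX[tgt[ok], ] <- dX[tgt[ok], , drop = FALSE] +
      dXcol[ok, cols, drop = FALSE]
  }
  list(dX = dX, dW = dW, db = db)
}

# ---- activations ------------------------------------------------------------

.LRELU_A <- 0.2
.lreluF <- function(x) { y <- x; neg <- x < 0; y[neg] <- .LRELU_A * x[neg]; y }
.lreluB <- function(dy, x) { g <- dy; neg <- x < 0; g[neg] <- .LRELU_A * dy[neg]; g }
.sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- batch <-> flat reshapes ------------------------------------------------

# (N*H*W) x C activation -> N x (H*W*C) per-sample flat matrix.
.flatten <- function(X, HW, N) {
  C <- ncol(X)
  arr <- array(X, dim = c(HW, N, C))
  matrix(aperm(arr, c(2, 1, 3)), N, HW * C)
}

.unflatten <- function(Xf, HW, N) {
  C <- ncol(Xf) / HW
  arr <- array(Xf, dim = c(N, HW, C))
  matrix(aperm(arr, c(2, 1, 3)), N * HW, C)
}

# Stack a list of H x W matrices into the (N*H*W) x 1 engine layout.
.stackPatches <- function(patches) {
  mats <- lapply(patches, .fd)
  matrix(unlist(mats, use.names = FALSE), ncol = 1L)
}

.unstackPatches <- function(X, H, W, N) {
  lapply(seq_len(N), function(n)
    matrix(X[((n - 1L) * H * W + 1L):(n * H * W), 1L], H, W))
}

# ---- parameter initialisation and Adam --------------------------------------

.heW <- function(fanIn, cout) matrix(rnorm(fanIn * cout, 0, sqrt(2 / fanIn)),
                                     fanIn, cout)

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# One Adam update; `direction = -1` descends the gradient, `+1` ascends.
adamStep <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8, direction = -1) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] + direction * lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
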