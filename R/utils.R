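# Internal helpers shared across modules.

# Run code with a local RNG state seeded by `seed`; the caller's RNG stream is
# left untouched so library calls stay reproducible without global surprises.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Accept ImageFrame or bare matrix.
.fd <- function(x) {
  if (is(x, "ImageFrame")) x@data else as.matrix(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Continuous pixel-centre coordinates of an (rows x cols) grid, pixel (r, c)
# 1-based -> (x, y) = (c - 0.5, r - 0.5). Returned in column-major pixel
# order, matching R matrix storage.
pixelCoords <- function(gridShape) {
  rows <- gridShape[1]; cols <- gridShape[2]
  list(
    x = rep(seq_len(cols) - 0.5, each = rows),
    y = rep(seq_len(rows) - 0.5, times = cols)
  )
}

# Logical matrix: pixel centre inside the FOV disc (boundary included).
fovMask <- function(gridShape, center, radius) {
  pc <- pixelCoords(gridShape)
  m <- (pc$x - center[1])^2 + (pc$y - center[2])^2 <= radius^2
  matrix(m, gridShape[1], gridShape[2])
}

# Default FOV for a grid: inscribed disc.
defaultFov <- function(gridShape) {
  list(center = c(gridShape[2] / 2, gridShape[1] / 2),
       radius = min(gridShape) / 2)
}
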