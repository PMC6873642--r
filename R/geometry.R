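# Planar geometry used by the acquisition simulator: Bowyer-Watson Delaunay
# triangulation of the fibre centres and barycentric point location. Written
# for bundles of up to a few thousand fibres; all loops are over triangles,
# pixels are handled vectorised.

# Circumcentre and squared circumradius of triangles given as index rows into
# point matrix p. Returns list(cx, cy, r2); degenerate (collinear) triangles
# get r2 = -Inf so they never capture a point.
.circumcircles <- function(tri, p) {
  ax <- p[tri[, 1], 1]; ay <- p[tri[, 1], 2]
  bx <- p[tri[, 2], 1]; by <- p[tri[, 2], 2]
  cx <- p[tri[, 3], 1]; cy <- p[tri[, 3], 2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  bad <- abs(d) < 1e-14
  d[bad] <- 1
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  r2 <- (ux - ax)^2 + (uy - ay)^2
  r2[bad] <- -Inf
  list(cx = ux, cy = uy, r2 = r2)
}

# Deterministic sub-nanometre symmetry-breaking offsets: regular lattices
# (e.g. an unjittered hexagonal bundle) have cocircular quadruples for which
# the Delaunay triangulation is not unique; a fixed pseudo-random perturbation
# picks one diagonal reproducibly. Only the topology is derived from the
# perturbed points; interpolation weights always use the true coordinates.
.tiebreak <- function(n, scale) {
  i <- seq_len(n)
  dx <- (((i * 7919L) %% 104729L) / 104729 - 0.5)
  dy <- (((i * 104729L) %% 7919L) / 7919 - 0.5)
  cbind(dx, dy) * (2e-9 * scale)
}

# Bowyer-Watson incremental Delaunay triangulation.
# pts: n x 2 matrix. Returns an m x 3 integer matrix of vertex indices.
delaunayTriangulate <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 3L) stop("Delaunay triangulation needs at least 3 points")
  rngx <- range(pts[, 1]); rngy <- range(pts[, 2])
  scale <- max(rngx[2] - rngx[1], rngy[2] - rngy[1], 1)
  # collinearity check on true coordinates
  if (n >= 3L) {
    a <- pts[1, ]
    rel <- sweep(pts, 2, a)
    cross <- rel[, 1] * rel[2, 2] - rel[, 2] * rel[2, 1]
    if (all(abs(cross) < 1e-9 * scale^2))
      stop("all fibre positions are collinear; triangulation is degenerate")
  }
  p <- pts + .tiebreak(n, scale)

  # super-triangle comfortably containing everything
  cx <- mean(rngx); cy <- mean(rngy)
  M <- 20 * scale
  p <- rbind(p,
             c(cx - 2 * M, cy - M),
             c(cx + 2 * M, cy - M),
             c(cx, cy + 2 * M))
  sup <- n + 1:3

  tri <- matrix(sup, 1, 3)
  cc <- .circumcircles(tri, p)

  for (i in seq_len(n)) {
    px <- p[i, 1]; py <- p[i, 2]
    inCirc <- (px - cc$cx)^2 + (py - cc$cy)^2 < cc$r2 * (1 + 1e-12)
    if (!any(inCirc)) {
      # numerical fallback: insert into the triangle whose circumcentre is
      # closest (should not happen with the tie-break perturbation)
      inCirc[which.min((px - cc$cx)^2 + (py - cc$cy)^2 - cc$r2)] <- TRUE
    }
    bad <- tri[inCirc, , drop = FALSE]
    # boundary of the cavity: edges used exactly once among bad triangles
    e <- rbind(bad[, c(1, 2)], bad[, c(2, 3)], bad[, c(3, 1)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    once <- !(key %in% key[duplicated(key)])
    boundary <- e[once, , drop = FALSE]

    newTri <- cbind(boundary, i)
    tri <- rbind(tri[!inCirc, , drop = FALSE], newTri)
    ccNew <- .circumcircles(newTri, p)
    cc <- list(cx = c(cc$cx[!inCirc], ccNew$cx),
               cy = c(cc$cy[!inCirc], ccNew$cy),
               r2 = c(cc$r2[!inCirc], ccNew$r2))
  }

  keep <- tri[, 1] <= n & tri[, 2] <= n & tri[, 3] <= n
  tri <- tri[keep, , drop = FALSE]
  # drop slivers that are degenerate in the TRUE coordinates
  area2 <- abs(
    (pts[tri[, 2], 1] - pts[tri[, 1], 1]) * (pts[tri[, 3], 2] - pts[tri[, 1], 2]) -
    (pts[tri[, 3], 1] - pts[tri[, 1], 1]) * (pts[tri[, 2], 2] - pts[tri[, 1], 2]))
  tri <- tri[area2 > 1e-12 * scale^2, , drop = FALSE]
  if (nrow(tri) == 0L)
    stop("triangulation degenerate: no non-degenerate triangles")
  storage.mode(tri) <- "integer"
  unname(tri)
}

# Adjacency list (by Delaunay edges) for a triangulation of n points.
.delaunayNeighbours <- function(tri, n) {
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  adj <- vector("list", n)
  for (k in seq_len(nrow(e))) {
    a <- e[k, 1]; b <- e[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, unique)
}

# Barycentric rasterisation: interpolate per-vertex values over a pixel grid.
# Returns a numeric vector over pixels (column-major), NA where no triangle
# contains the pixel centre.
.rasterizeTriangulation <- function(tri, pts, vals, gridShape) {
  rows <- gridShape[1]; cols <- gridShape[2]
  out <- rep(NA_real_, rows * cols)
  tol <- -1e-9
  for (k in seq_len(nrow(tri))) {
    a <- tri[k, 1]; b <- tri[k, 2]; c3 <- tri[k, 3]
    ax <- pts[a, 1]; ay <- pts[a, 2]
    bx <- pts[b, 1]; by <- pts[b, 2]
    cxx <- pts[c3, 1]; cyy <- pts[c3, 2]
    # candidate pixels: bounding box (pixel centre (c-0.5, r-0.5))
    c0 <- max(1L, as.integer(ceiling(min(ax, bx, cxx) + 0.5)))
    c1 <- min(cols, as.integer(floor(max(ax, bx, cxx) + 0.5)))
    r0 <- max(1L, as.integer(ceiling(min(ay, by, cyy) + 0.5)))
    r1 <- min(rows, as.integer(floor(max(ay, by, cyy) + 0.5)))
    if (c0 > c1 || r0 > r1) next
    ccols <- c0:c1; rrows <- r0:r1
    x <- rep(ccols - 0.5, each = length(rrows))
    y <- rep(rrows - 0.5, times = length(ccols))
    idx <- rep((ccols - 1L) * rows, each = length(rrows)) + rrows
    free <- is.na(out[idx])
    if (!any(free)) next
    x <- x[free]; y <- y[free]; idx <- idx[free]
    det <- (by - cyy) * (ax - cxx) + (cxx - bx) * (ay - cyy)
    l1 <- ((by - cyy) * (x - cxx) + (cxx - bx) * (y - cyy)) / det
    l2 <- ((cyy - ay) * (x - cxx) + (ax - cxx) * (y - cyy)) / det
    l3 <- 1 - l1 - l2
    ok <- l1 >= tol & l2 >= tol & l3 >= tol
    if (!any(ok)) next
    out[idx[ok]] <- l1[ok] * vals[a] + l2[ok] * vals[b] + l3[ok] * vals[c3]
  }
  out
}
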