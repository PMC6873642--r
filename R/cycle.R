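# Physically-inspired cycle block: the fixed (non-trainable) operator that
# re-acquires a super-resolved patch through the bundle geometry and the
# matching normalized acquisition vector for the input LR patch.

# Min-max normalization to [0, 1] over the real entries. Degenerate case
# (max == min, e.g. a constant patch) maps to all zeros so real entries stay
# indistinguishable from zero padding, matching the 0-padding convention.
# Missing entries (NA) also map to 0.
.minmax01 <- function(v) {
  ok <- !is.na(v)
  if (!any(ok)) return(rep(0, length(v)))
  mn <- min(v[ok]); mx <- max(v[ok])
  out <- if (mx > mn) (v - mn) / (mx - mn) else rep(0, length(v))
  out[!ok] <- 0
  out
}

#' Crop a VoronoiMap to a patch window
#'
#' Slices the label image to the given window and recomputes per-fibre pixel
#' counts inside it. Fibres whose cells fall entirely outside the window keep
#' a zero count and are treated as absent by [voronoiVectorize()].
#'
#' @param vmap a \linkS4class{VoronoiMap}.
#' @param rowOffset,colOffset 0-based offsets of the window's top-left corner.
#' @param size window size in pixels (square) or \code{(rows, cols)}.
#' @return a \linkS4class{VoronoiMap} over the window grid.
#' @export
cropVoronoiMap <- function(vmap, rowOffset, colOffset, size) {
  if (length(size) == 1L) size <- c(size, size)
  lab <- cellLabels(vmap)
  stopifnot(rowOffset >= 0, colOffset >= 0,
            rowOffset + size[1] <= nrow(lab),
            colOffset + size[2] <= ncol(lab))
  sub <- lab[rowOffset + seq_len(size[1]), colOffset + seq_len(size[2]),
             drop = FALSE]
  nf <- nFibres(vmap)
  inside <- sub >= 0L
  new("VoronoiMap", labels = sub,
      cellSizes = tabulate(sub[inside] + 1L, nbins = nf))
}

#' Voronoi vectorization of a (super-resolved) patch
#'
#' The fixed down-sampling operator of the cycle block: averages the patch
#' pixels within each Voronoi cell (imitating the point spread of the fibre
#' acquisition), min-max normalizes the per-cell means to \code{[0, 1]}, and
#' zero-pads the vector to the fixed length \code{N_F}. Cells with no pixel
#' inside the patch contribute padding slots; cells partially inside are
#' averaged over their inside pixels only.
#'
#' @param patch an \linkS4class{ImageFrame} (or matrix), same shape as
#'   \code{vmap}.
#' @param vmap a \linkS4class{VoronoiMap} over the patch grid (typically from
#'   [cropVoronoiMap()]).
#' @param paddedLen target vector length \code{N_F}; must be at least the
#'   number of fibres visible in the patch.
#' @return a normalized, padded \linkS4class{FibreSignalVector}.
#' @export
voronoiVectorize <- function(patch, vmap, paddedLen) {
  img <- .fd(patch)
  lab <- cellLabels(vmap)
  if (!all(dim(img) == dim(lab)))
    stop("patch shape does not match Voronoi map shape")
  counts <- cellSizes(vmap)
  present <- which(counts > 0L)
  if (paddedLen < length(present))
    stop("paddedLen (", paddedLen, ") smaller than the number of fibres ",
         "visible in the patch (", length(present), ")")
  inside <- lab >= 0L
  # base mean() (two-pass with correction) keeps cell means exact when a cell
  # is constant, which the painted-cell fixed-point property relies on
  byCell <- split(img[inside], lab[inside] + 1L)
  means <- vapply(byCell[as.character(present)], mean, 0)
  FibreSignalVector(.minmax01(means), paddedLength = paddedLen,
                    normalized = TRUE, fibreIds = present - 1L)
}

#' Normalized acquisition vector V(I_LR) of a low-resolution patch
#'
#' Returns the per-fibre acquisition vector in the same normalized, padded
#' form as [voronoiVectorize()], so the two sides of the cycle-consistency
#' loss are directly comparable. When the raw fibre signals are available
#' (simulated or recorded) they are used directly; otherwise the function
#' falls back to Voronoi vectorization of the reconstructed LR patch, which
#' approximates the raw signals up to the interpolation error of the
#' reconstruction.
#'
#' @param lr reconstructed LR patch (\linkS4class{ImageFrame} or matrix);
#'   required for the fallback path.
#' @param vmap \linkS4class{VoronoiMap} over the patch grid; selects which
#'   fibres are visible. May be \code{NULL} on the raw path, in which case all
#'   raw entries are taken as visible.
#' @param rawSignals optional raw \linkS4class{FibreSignalVector} for the full
#'   bundle (one entry per fibre of \code{vmap}).
#' @param paddedLen target vector length \code{N_F}.
#' @return a normalized, padded \linkS4class{FibreSignalVector}.
#' @export
acquisitionVector <- function(lr = NULL, vmap = NULL, rawSignals = NULL,
                              paddedLen) {
  if (is.null(rawSignals)) {
    if (is.null(lr) || is.null(vmap))
      stop("either rawSignals or both lr and vmap must be supplied")
    return(voronoiVectorize(lr, vmap, paddedLen))
  }
  stopifnot(is(rawSignals, "FibreSignalVector"))
  n <- nFibres(rawSignals)
  raw <- signalValues(rawSignals)[seq_len(n)]
  if (is.null(vmap)) {
    present <- seq_len(n)
  } else {
    if (n != nFibres(vmap))
      stop("rawSignals fibre count (", n, ") does not match Voronoi map (",
           nFibres(vmap), ")")
    present <- which(cellSizes(vmap) > 0L)
  }
  if (paddedLen < length(present))
    stop("paddedLen smaller than the number of visible fibres")
  FibreSignalVector(.minmax01(raw[present]), paddedLength = paddedLen,
                    normalized = TRUE, fibreIds = present - 1L)
}
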