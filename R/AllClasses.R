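#' @import methods
NULL

#' ImageFrame: a 2-D grayscale intensity grid
#'
#' Container for a single grayscale frame. Intensities are stored as a
#' numeric matrix, by convention in \code{[0, 1]} after preprocessing
#' (\code{\link{preprocessSequence}}). The \code{role} tag records whether the
#' frame stands for an estimated high-resolution reference (\code{"HR"}), a
#' reconstructed low-resolution pCLE frame (\code{"LR"}) or a super-resolved
#' output (\code{"SR"}).
#'
#' @slot data numeric matrix of pixel intensities (rows x cols).
#' @slot role character tag, one of \code{"HR"}, \code{"LR"}, \code{"SR"} or
#'   \code{""}.
#'
#' @seealso [ImageFrame()], [frameData()], [frameRole()]
#' @export
setClass("ImageFrame",
  representation(data = "matrix", role = "character"),
  prototype(data = matrix(0, 1, 1), role = "")
)

setValidity("ImageFrame", function(object) {
  msg <- character()
  if (!is.numeric(object@data)) msg <- c(msg, "data must be a numeric matrix")
  if (length(object@role) != 1L ||
      !object@role %in% c("HR", "LR", "SR", "")) {
    msg <- c(msg, "role must be one of 'HR', 'LR', 'SR', ''")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ImageFrame
#'
#' @param data numeric matrix of intensities.
#' @param role frame role tag: \code{"HR"}, \code{"LR"}, \code{"SR"} or
#'   \code{""}.
#' @return an \linkS4class{ImageFrame}.
#' @examples
#' f <- ImageFrame(matrix(runif(64), 8, 8), role = "HR")
#' dim(frameData(f))
#' @export
ImageFrame <- function(data, role = "") {
  if (is(data, "ImageFrame")) return(data)
  new("ImageFrame", data = as.matrix(data), role = role)
}

#' FibreLayout: fibre-centre positions of a bundle
#'
#' The physical fibre bundle: an irregular set of fibre-centre coordinates in
#' pixel units together with the circular field of view (FOV) that the bundle
#' images. Coordinates follow the pixel-centre convention: the pixel in row
#' \code{r}, column \code{c} (1-based) has continuous coordinates
#' \code{(x, y) = (c - 0.5, r - 0.5)}, so a \code{64 x 64} grid spans
#' \code{[0, 64] x [0, 64]} with centre \code{(32, 32)}.
#'
#' @slot positions numeric matrix with columns \code{x}, \code{y}; one row per
#'   fibre, all strictly inside the FOV disc and pairwise distinct.
#' @slot fovCenter numeric length-2, centre \code{(x, y)} of the FOV disc.
#' @slot fovRadius positive scalar, FOV radius in pixels.
#'
#' @seealso [generateFibreLayout()], [computeVoronoiMap()]
#' @export
setClass("FibreLayout",
  representation(positions = "matrix", fovCenter = "numeric",
                 fovRadius = "numeric")
)

setValidity("FibreLayout", function(object) {
  p <- object@positions
  msg <- character()
  if (ncol(p) != 2L) msg <- c(msg, "positions must have two columns (x, y)")
  if (nrow(p) < 1L) msg <- c(msg, "at least one fibre is required")
  if (length(object@fovCenter) != 2L) msg <- c(msg, "fovCenter must be (x, y)")
  if (length(object@fovRadius) != 1L || object@fovRadius <= 0)
    msg <- c(msg, "fovRadius must be a positive scalar")
  if (!length(msg)) {
    d2 <- (p[, 1] - object@fovCenter[1])^2 + (p[, 2] - object@fovCenter[2])^2
    if (any(d2 >= object@fovRadius^2))
      msg <- c(msg, "all fibre positions must lie strictly inside the FOV disc")
    if (nrow(p) > 1L && any(dist(p) == 0))
      msg <- c(msg, "fibre positions must be pairwise distinct")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FibreLayout
#'
#' @param positions numeric matrix (or two-column data.frame) of fibre-centre
#'   coordinates, columns \code{x}, \code{y}, pixel units.
#' @param fovCenter centre of the circular field of view; defaults to the
#'   centroid bounding all fibres if omitted.
#' @param fovRadius radius of the field of view in pixels.
#' @return a \linkS4class{FibreLayout}.
#' @export
FibreLayout <- function(positions, fovCenter, fovRadius) {
  positions <- as.matrix(positions)
  colnames(positions) <- c("x", "y")
  storage.mode(positions) <- "double"
  new("FibreLayout", positions = positions,
      fovCenter = as.numeric(fovCenter), fovRadius = as.numeric(fovRadius))
}

#' VoronoiMap: per-pixel nearest-fibre labels
#'
#' The sampling partition induced by a \linkS4class{FibreLayout} on a pixel
#' grid. Each pixel inside the field of view carries the 0-based index of its
#' nearest fibre (Euclidean distance between pixel centre and fibre centre,
#' ties broken by the lowest fibre index); pixels outside the FOV disc carry
#' the sentinel \code{-1}.
#'
#' @slot labels integer matrix of 0-based fibre indices, \code{-1} outside the
#'   FOV.
#' @slot cellSizes integer vector, pixels per fibre cell (may contain zeros
#'   for fibres whose cell holds no pixel of this grid).
#'
#' @seealso [computeVoronoiMap()], [cellLabels()], [cellSizes()]
#' @export
setClass("VoronoiMap",
  representation(labels = "matrix", cellSizes = "integer")
)

setValidity("VoronoiMap", function(object) {
  msg <- character()
  if (!is.integer(object@labels)) msg <- c(msg, "labels must be integer")
  if (!length(msg)) {
    inside <- object@labels >= 0L
    if (sum(object@cellSizes) != sum(inside))
      msg <- c(msg, "cellSizes must sum to the number of in-FOV pixels")
    if (any(object@labels[inside] >= length(object@cellSizes)))
      msg <- c(msg, "labels exceed the number of fibres")
  }
  if (length(msg)) msg else TRUE
})

#' FibreSignalVector: per-fibre scalar signals
#'
#' Holds one scalar per fibre: either the raw acquisition signals
#' \code{V(I_LR)} produced by the simulator (unnormalized, unpadded) or their
#' normalized, zero-padded form used by the cycle-consistency loss. When
#' \code{normalized} is \code{TRUE} all real entries lie in \code{[0, 1]} and
#' entries beyond \code{nFibres} are exactly zero padding up to
#' \code{paddedLength} (the fixed vector length \code{N_F}).
#'
#' @slot values numeric vector of length \code{paddedLength}; the first
#'   \code{nFibres} entries are real signals (possibly \code{NA} for fibres
#'   flagged missing in raw vectors), the remainder zero padding.
#' @slot nFibres number of real (non-padding) entries.
#' @slot paddedLength total vector length \code{N_F}.
#' @slot normalized whether min-max normalization to \code{[0, 1]} has been
#'   applied.
#' @slot fibreIds 0-based ids of the fibres behind the real entries, in
#'   increasing order.
#' @export
setClass("FibreSignalVector",
  representation(values = "numeric", nFibres = "integer",
                 paddedLength = "integer", normalized = "logical",
                 fibreIds = "integer")
)

setValidity("FibreSignalVector", function(object) {
  msg <- character()
  n <- object@nFibres
  if (object@paddedLength < n)
    msg <- c(msg, "paddedLength must be >= nFibres")
  if (length(object@values) != object@paddedLength)
    msg <- c(msg, "values length must equal paddedLength")
  if (length(object@fibreIds) != n)
    msg <- c(msg, "fibreIds length must equal nFibres")
  if (!length(msg) && object@normalized) {
    real <- object@values[seq_len(n)]
    if (anyNA(real) || any(real < 0 | real > 1))
      msg <- c(msg, "normalized real entries must lie in [0, 1]")
  }
  if (!length(msg) && object@paddedLength > n) {
    pad <- object@values[(n + 1L):object@paddedLength]
    if (any(pad != 0)) msg <- c(msg, "padding entries must be exactly 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FibreSignalVector
#'
#' @param values numeric vector of real per-fibre signals (no padding).
#' @param paddedLength target length \code{N_F}; defaults to
#'   \code{length(values)} (no padding).
#' @param normalized whether \code{values} are already min-max normalized.
#' @param fibreIds 0-based fibre ids of the entries; defaults to
#'   \code{0:(n-1)}.
#' @return a \linkS4class{FibreSignalVector}.
#' @export
FibreSignalVector <- function(values, paddedLength = length(values),
                              normalized = FALSE,
                              fibreIds = seq_along(values) - 1L) {
  n <- length(values)
  paddedLength <- as.integer(paddedLength)
  if (paddedLength < n)
    stop("paddedLength (", paddedLength, ") smaller than fibre count (", n, ")")
  v <- c(as.numeric(values), rep(0, paddedLength - n))
  new("FibreSignalVector", values = v, nFibres = as.integer(n),
      paddedLength = paddedLength, normalized = isTRUE(normalized),
      fibreIds = as.integer(fibreIds))
}

#' LossBreakdown: the three generator loss terms and their weighted total
#'
#' @slot lVec cycle-consistency (Voronoi vectorization) mean squared error.
#' @slot lAdv adversarial term \code{-log D(SR(x))}.
#' @slot lReg row/column-mean regularizer.
#' @slot weights numeric length-3 weights \code{(w_vec, w_adv, w_reg)}.
#' @slot total weighted sum of the three terms.
#' @export
setClass("LossBreakdown",
  representation(lVec = "numeric", lAdv = "numeric", lReg = "numeric",
                 weights = "numeric", total = "numeric")
)

setValidity("LossBreakdown", function(object) {
  msg <- character()
  if (length(object@weights) != 3L) msg <- c(msg, "weights must have length 3")
  if (any(c(object@lVec, object@lAdv, object@lReg) < 0))
    msg <- c(msg, "loss terms must be non-negative")
  expected <- sum(object@weights * c(object@lVec, object@lAdv, object@lReg))
  if (!length(msg) && abs(object@total - expected) > 1e-9 * max(1, abs(expected)))
    msg <- c(msg, "total must equal the weighted sum of the terms")
  if (length(msg)) msg else TRUE
})

#' MetricsReport: per-image quality metrics plus aggregates
#'
#' One row per evaluated image with SSIM against the HR reference, the global
#' contrast factor improvements against the HR reference and against the input
#' LR, and the composite score; aggregate mean and standard deviation per
#' metric, mirroring the usual results-table layout.
#'
#' @slot rows data.frame with columns \code{image_id}, \code{ssim_hr},
#'   \code{dgcf_hr}, \code{dgcf_lr}, \code{tot_cs}.
#' @slot aggregates data.frame with columns \code{metric}, \code{mean},
#'   \code{sd}.
#' @slot caseStudy evaluation split tag, e.g. \code{"CS1"} (grouped by video)
#'   or \code{"CS2"} (grouped by patient).
#' @export
setClass("MetricsReport",
  representation(rows = "data.frame", aggregates = "data.frame",
                 caseStudy = "character")
)

setValidity("MetricsReport", function(object) {
  need <- c("image_id", "ssim_hr", "dgcf_hr", "dgcf_lr", "tot_cs")
  if (!all(need %in% names(object@rows)))
    return(paste("rows must contain columns:", paste(need, collapse = ", ")))
  TRUE
})
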