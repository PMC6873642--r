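# Quantitative image-quality evaluation: SSIM against the HR reference, the
# reference-free global contrast factor (GCF) and its improvements against
# the HR reference and the input LR, the composite score, per-method report
# aggregation and the paired significance test.

# Gaussian window, length n, standard deviation s, normalized to sum 1.
.gaussWin <- function(n = 11L, s = 1.5) {
  x <- seq_len(n) - (n + 1) / 2
  g <- exp(-x^2 / (2 * s^2))
  g / sum(g)
}

# Valid 2-D separable filtering: banded convolution matrices applied on both
# sides; output is (H-n+1) x (W-n+1).
.validFilter <- function(m, g) {
  n <- length(g)
  H <- nrow(m); W <- ncol(m)
  K <- function(size) {
    out <- matrix(0, size - n + 1L, size)
    for (i in seq_len(size - n + 1L)) out[i, i:(i + n - 1L)] <- g
    out
  }
  K(H) %*% m %*% t(K(W))
}

#' Structural similarity (SSIM) between two frames
#'
#' Standard SSIM with an 11x11 Gaussian window of standard deviation 1.5,
#' stabilizers \code{K1 = 0.01}, \code{K2 = 0.03} and dynamic range 1
#' (frames are expected in \code{[0, 1]}), averaged over the valid filter
#' region of the frame.
#'
#' @param a,b \linkS4class{ImageFrame}s or matrices of identical shape, at
#'   least 11 x 11.
#' @return scalar in \code{(-1, 1]}; 1 iff the frames are identical.
#' @export
metricSSIM <- function(a, b) {
  x <- .fd(a); y <- .fd(b)
  if (!all(dim(x) == dim(y))) stop("frames have different shapes")
  stopifnot(nrow(x) >= 11L, ncol(x) >= 11L)
  g <- .gaussWin()
  C1 <- 0.01^2; C2 <- 0.03^2
  mu1 <- .validFilter(x, g); mu2 <- .validFilter(y, g)
  s1 <- .validFilter(x * x, g) - mu1^2
  s2 <- .validFilter(y * y, g) - mu2^2
  s12 <- .validFilter(x * y, g) - mu1 * mu2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1^2 + mu2^2 + C1) * (s1 + s2 + C2)
  mean(num / den)
}

# Mean local contrast of a perceptual-luminance image: per pixel, the mean
# absolute difference to its existing 4-neighbours, averaged over pixels.
.localContrast <- function(L) {
  H <- nrow(L); W <- ncol(L)
  S <- matrix(0, H, W)
  Ncnt <- matrix(0, H, W)
  if (H > 1) {
    d <- abs(L[-1, , drop = FALSE] - L[-H, , drop = FALSE])
    S[-1, ] <- S[-1, ] + d; S[-H, ] <- S[-H, ] + d
    Ncnt[-1, ] <- Ncnt[-1, ] + 1; Ncnt[-H, ] <- Ncnt[-H, ] + 1
  }
  if (W > 1) {
    d <- abs(L[, -1, drop = FALSE] - L[, -W, drop = FALSE])
    S[, -1] <- S[, -1] + d; S[, -W] <- S[, -W] + d
    Ncnt[, -1] <- Ncnt[, -1] + 1; Ncnt[, -W] <- Ncnt[, -W] + 1
  }
  mean(S / Ncnt)
}

#' Global contrast factor (GCF)
#'
#' Reference-free contrast metric: intensities (in \code{[0, 1]}) are mapped
#' through gamma 2.2 to linear luminance \code{l} and then to perceptual
#' luminance \code{L = 100 * sqrt(l)}; the local contrast at one resolution is
#' the mean over pixels of the mean absolute \code{L}-difference to the
#' existing 4-neighbours; contrasts are computed at 9 dyadic superpixel
#' resolutions (blocks of 1, 2, 4, ..., 256 pixels formed by averaging the
#' gamma-encoded intensities, truncating to the largest divisible region) and
#' combined as \code{GCF = sum_i w_i C_i} with the published weighting
#' polynomial \code{w_i = (-0.406385 i/9 + 0.334573) i/9 + 0.0877526}.
#' Levels whose downsampled image is smaller than 2 pixels in either direction
#' contribute zero contrast.
#'
#' @param img \linkS4class{ImageFrame} or matrix with values in \code{[0, 1]},
#'   at least 2 x 2.
#' @return non-negative scalar; 0 for constant images.
#' @export
metricGCF <- function(img) {
  m <- .fd(img)
  if (nrow(m) < 2L || ncol(m) < 2L) stop("image must be at least 2 x 2")
  gcf <- 0
  for (i in 1:9) {
    b <- 2L^(i - 1L)
    ds <- .blockMean(m, b)
    ci <- if (is.null(ds) || nrow(ds) < 2L || ncol(ds) < 2L) 0
          else .localContrast(100 * ds^1.1)   # 100*sqrt(ds^2.2)
    wi <- (-0.406385 * i / 9 + 0.334573) * i / 9 + 0.0877526
    gcf <- gcf + wi * ci
  }
  gcf
}

#' Contrast improvement of a test frame over a reference
#'
#' \code{GCF(test) - GCF(reference)}; positive values mean the test frame has
#' more global contrast than the reference.
#'
#' @param test,reference frames valid for [metricGCF()].
#' @return scalar.
#' @export
deltaGCF <- function(test, reference) {
  metricGCF(test) - metricGCF(reference)
}

#' Composite quality score
#'
#' Averages the window-normalized SSIM and contrast-improvement terms:
#' \code{mean((ssim - 0.6)/0.4, (dgcfHr + 0.5)/1.82)}. SSIM alone is not
#' reliable when the HR reference is itself estimated, and contrast alone can
#' be gamed by adding high-frequency noise; the composite balances the two.
#' Values outside the nominal normalization windows are allowed.
#'
#' @param ssim SSIM of the test frame against the HR reference.
#' @param dgcfHr GCF improvement of the test frame over the HR reference.
#' @return scalar; strictly increasing in both arguments.
#' @examples
#' totCS(0.6, -0.5)  # both anchors -> 0
#' @export
totCS <- function(ssim, dgcfHr) {
  ((ssim - 0.6) / 0.4 + (dgcfHr + 0.5) / 1.82) / 2
}

#' Evaluate a super-resolution method over aligned frame triples
#'
#' For every image id computes SSIM against the HR reference, the GCF
#' improvements against the HR reference and against the input LR, and the
#' composite score, then aggregates each metric as mean and standard
#' deviation.
#'
#' @param srFrames,hrFrames,lrFrames lists of frames aligned by name (or by
#'   position when unnamed).
#' @param caseStudy optional split tag, e.g. \code{"CS1"} or \code{"CS2"}.
#' @return a \linkS4class{MetricsReport}.
#' @export
evaluateMethod <- function(srFrames, hrFrames, lrFrames, caseStudy = "") {
  n <- length(srFrames)
  stopifnot(length(hrFrames) == n, length(lrFrames) == n, n >= 1)
  ids <- names(srFrames)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (!is.null(names(hrFrames)) && !identical(names(hrFrames), ids))
    stop("hrFrames ids do not match srFrames ids")
  if (!is.null(names(lrFrames)) && !identical(names(lrFrames), ids))
    stop("lrFrames ids do not match srFrames ids")

  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    ssim <- metricSSIM(srFrames[[i]], hrFrames[[i]])
    gSr <- metricGCF(srFrames[[i]])
    dHr <- gSr - metricGCF(hrFrames[[i]])
    dLr <- gSr - metricGCF(lrFrames[[i]])
    data.frame(image_id = ids[i], ssim_hr = ssim, dgcf_hr = dHr,
               dgcf_lr = dLr, tot_cs = totCS(ssim, dHr),
               stringsAsFactors = FALSE)
  }))
  sd0 <- function(x) if (length(x) > 1L) sd(x) else 0
  metrics <- c("ssim_hr", "dgcf_hr", "dgcf_lr", "tot_cs")
  agg <- data.frame(metric = metrics,
                    mean = vapply(metrics, function(m) mean(rows[[m]]), 0),
                    sd = vapply(metrics, function(m) sd0(rows[[m]]), 0),
                    row.names = NULL, stringsAsFactors = FALSE)
  new("MetricsReport", rows = rows, aggregates = agg, caseStudy = caseStudy)
}

#' Paired significance test between two methods
#'
#' Two-sided paired t-test on per-image metric differences. A zero-variance
#' difference vector (e.g. identical metric lists) is flagged degenerate and
#' returns \code{t = 0} with \code{p = NA}.
#'
#' @param rowsA,rowsB numeric vectors of a per-image metric, paired by
#'   position, equal length >= 2.
#' @return list with \code{statistic}, \code{p.value}, \code{degenerate}.
#' @export
pairedSignificance <- function(rowsA, rowsB) {
  stopifnot(length(rowsA) == length(rowsB), length(rowsA) >= 2)
  d <- rowsA - rowsB
  if (sd(d) == 0)
    return(list(statistic = 0, p.value = NA_real_, degenerate = TRUE))
  tt <- t.test(rowsA, rowsB, paired = TRUE)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       degenerate = FALSE)
}

#' Aggregate mean-opinion-score tables
#'
#' Plain mean/sd aggregation of externally collected MOS ratings per method
#' and question; no questionnaire logic is provided.
#'
#' @param scores data.frame with columns \code{method}, \code{question},
#'   \code{score}.
#' @return data.frame with per (method, question) \code{mean} and \code{sd}.
#' @export
mosAggregate <- function(scores) {
  stopifnot(all(c("method", "question", "score") %in% names(scores)))
  agg <- aggregate(score ~ method + question, data = scores,
                   FUN = function(x) c(mean = mean(x), sd = sd(x)))
  data.frame(method = agg$method, question = agg$question,
             mean = agg$score[, "mean"], sd = agg$score[, "sd"],
             stringsAsFactors = FALSE)
}
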