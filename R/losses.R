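# Training objectives: cycle-consistency MSE over the fibre vectors, the
# non-saturating adversarial term, the row/column-mean regularizer, their
# weighted combination for the generator, and the discriminator objective.

.PROB_EPS <- 1e-7

#' Cycle-consistency loss over fibre signal vectors
#'
#' Mean squared difference between the normalized acquisition vector
#' \code{V(I_LR)} and the Voronoi vectorization \code{V_hat(SR(I_LR))},
#' averaged over all \code{N_F} entries (padding included; both paddings are
#' zero so they contribute nothing).
#'
#' @param vLr,vSr normalized \linkS4class{FibreSignalVector}s padded to the
#'   same \code{N_F}.
#' @return non-negative scalar.
#' @export
lossVec <- function(vLr, vSr) {
  a <- if (is(vLr, "FibreSignalVector")) signalValues(vLr) else as.numeric(vLr)
  b <- if (is(vSr, "FibreSignalVector")) signalValues(vSr) else as.numeric(vSr)
  if (length(a) != length(b))
    stop("vector lengths differ (", length(a), " vs ", length(b),
         "); both sides must be padded to the same N_F")
  mean((a - b)^2)
}

#' Adversarial loss for the generator
#'
#' The non-saturating form \code{-log D(SR(x))}: instead of minimizing
#' \code{log(1 - D(SR(x)))} the generator maximizes the log-probability that
#' the discriminator assigns to its output, which keeps gradients useful when
#' the discriminator is confident. Probabilities are clamped to
#' \code{[1e-7, 1]} before the log.
#'
#' @param dProb discriminator probability (or vector of probabilities; the
#'   mean loss is returned).
#' @return non-negative scalar.
#' @export
lossAdv <- function(dProb) {
  mean(-log(clamp(dProb, .PROB_EPS, 1)))
}

#' Row/column-mean regularizer
#'
#' Because each Voronoi vectorization is normalized to \code{[0, 1]}, the
#' cycle loss alone is blind to global histogram stretches of the generator
#' output. This term restores the intensity distribution by penalizing squared
#' differences between per-row means and per-column means of the SR output and
#' the input LR patch.
#'
#' @param lr,sr \linkS4class{ImageFrame}s or matrices of identical shape.
#' @return non-negative scalar.
#' @export
lossReg <- function(lr, sr) {
  a <- .fd(lr); b <- .fd(sr)
  if (!all(dim(a) == dim(b))) stop("lr and sr shapes differ")
  mean((rowMeans(b) - rowMeans(a))^2) + mean((colMeans(b) - colMeans(a))^2)
}

#' Composite generator loss
#'
#' Assembles the three generator terms: the Voronoi vectorization of
#' \code{sr} is computed with the patch's Voronoi map and compared with the
#' acquisition vector \code{vLr} (cycle consistency), the adversarial term is
#' taken from the supplied discriminator probability, and the row/column-mean
#' regularizer compares \code{sr} with \code{lr}. The total is the weighted
#' sum; the default weights \code{(1, 1, 1)} give the plain unweighted sum.
#'
#' @param lr,sr input LR patch and generator output, identical shape.
#' @param vLr normalized acquisition vector of the LR patch.
#' @param vmap \linkS4class{VoronoiMap} of the patch grid.
#' @param dProb discriminator probability for \code{sr}.
#' @param weights numeric length-3 \code{(w_vec, w_adv, w_reg)}.
#' @return a \linkS4class{LossBreakdown}.
#' @export
generatorLoss <- function(lr, sr, vLr, vmap, dProb, weights = c(1, 1, 1)) {
  stopifnot(length(weights) == 3)
  vSr <- voronoiVectorize(sr, vmap, paddedLength(vLr))
  lv <- lossVec(vLr, vSr)
  la <- lossAdv(dProb)
  lrg <- lossReg(lr, sr)
  total <- sum(weights * c(lv, la, lrg))
  new("LossBreakdown", lVec = lv, lAdv = la, lReg = lrg,
      weights = as.numeric(weights), total = total)
}

#' Discriminator objective
#'
#' The value \code{log(1 - D(SR(x))) + log D(y)} that the discriminator
#' maximizes (its negation is the usual binary cross-entropy with labels
#' real = 1, fake = 0). Probabilities are clamped to
#' \code{[1e-7, 1 - 1e-7]}. Vector inputs are averaged over the batch.
#'
#' @param dReal discriminator probability/ies on real target-domain patches.
#' @param dFake discriminator probability/ies on generated patches.
#' @return scalar objective value (higher is better for the discriminator).
#' @export
discriminatorObjective <- function(dReal, dFake) {
  dr <- clamp(dReal, .PROB_EPS, 1 - .PROB_EPS)
  df <- clamp(dFake, .PROB_EPS, 1 - .PROB_EPS)
  mean(log(1 - df)) + mean(log(dr))
}
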