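# Preprocessing and dataset assembly: sequence intensity normalization, FOV
# patch extraction, target-domain construction and grouped splits.

# Mean over b x b blocks, truncating to the largest divisible region.
.blockMean <- function(m, b) {
  if (b == 1L) return(m)
  H2 <- nrow(m) %/% b; W2 <- ncol(m) %/% b
  if (H2 < 1L || W2 < 1L) return(NULL)
  m <- m[seq_len(H2 * b), seq_len(W2 * b), drop = FALSE]
  rowsDown <- matrix(colMeans(matrix(m, nrow = b)), nrow = H2)   # H2 x (W2*b)
  t(matrix(colMeans(matrix(t(rowsDown), nrow = b)), nrow = W2))  # H2 x W2
}

#' Normalize a frame sequence
#'
#' Two-stage intensity normalization applied before patch extraction:
#' (1) a global z-score using the mean and standard deviation pooled over the
#' whole sequence, then (2) an independent min-max rescale of every frame to
#' \code{[0, 1]}. A frame that is constant after stage 1 maps to all 0.5.
#'
#' @param frames list of \linkS4class{ImageFrame}s or matrices.
#' @return list of \linkS4class{ImageFrame}s, roles preserved.
#' @export
preprocessSequence <- function(frames) {
  stopifnot(length(frames) >= 1)
  mats <- lapply(frames, .fd)
  allv <- unlist(lapply(mats, as.vector), use.names = FALSE)
  if (!all(is.finite(allv))) stop("frames contain non-finite intensities")
  mu <- mean(allv)
  sdv <- sd(allv)
  if (sdv == 0) stop("zero global variance: the sequence is constant")
  lapply(seq_along(mats), function(i) {
    z <- (mats[[i]] - mu) / sdv
    mn <- min(z); mx <- max(z)
    out <- if (mx > mn) (z - mn) / (mx - mn) else z * 0 + 0.5
    role <- if (is(frames[[i]], "ImageFrame")) frameRole(frames[[i]]) else ""
    ImageFrame(out, role = role)
  })
}

#' Extract non-overlapping patches inside the field of view
#'
#' Tiles the frame on a non-overlapping \code{patchSize} grid anchored at the
#' top-left corner and keeps only tiles lying fully inside the FOV mask.
#' Each returned patch carries an \code{offset} attribute with the 0-based
#' \code{(rowOffset, colOffset)} of its top-left corner, so the matching
#' window of a \linkS4class{VoronoiMap} can be recovered with
#' [cropVoronoiMap()].
#'
#' @param frame \linkS4class{ImageFrame} or matrix.
#' @param fovMask logical matrix of the frame's shape, or \code{NULL} to keep
#'   every tile.
#' @param patchSize tile side in pixels.
#' @return list of \linkS4class{ImageFrame} patches (possibly empty).
#' @export
extractPatches <- function(frame, fovMask = NULL, patchSize = 64L) {
  img <- .fd(frame)
  H <- nrow(img); W <- ncol(img)
  stopifnot(H >= patchSize, W >= patchSize)
  role <- if (is(frame, "ImageFrame")) frameRole(frame) else ""
  out <- list()
  for (r0 in seq(0L, H - patchSize, by = patchSize))
    for (c0 in seq(0L, W - patchSize, by = patchSize)) {
      rr <- r0 + seq_len(patchSize); cc <- c0 + seq_len(patchSize)
      if (!is.null(fovMask) && !all(fovMask[rr, cc])) next
      p <- ImageFrame(img[rr, cc], role = role)
      attr(p, "offset") <- c(rowOffset = r0, colOffset = c0)
      out[[length(out) + 1L]] <- p
    }
  out
}

#' Assemble a target domain for adversarial training
#'
#' Builds the pool of "real" high-resolution patches the discriminator sees.
#' Four kinds are supported: \code{"nat"} tiles grayscale natural(-like)
#' images; \code{"orig"} tiles HR reference frames; \code{"syn"} tiles HR
#' frames and records the aligned simulated-LR patch alongside (the pairing is
#' unused by the unsupervised loss); \code{"res"} cuts regions of
#' \code{4 * patchSize} from LR frames and downsamples them by a factor of 4
#' with area averaging, exploiting cross-scale patch recurrence.
#'
#' @param kind one of \code{"nat"}, \code{"orig"}, \code{"syn"}, \code{"res"}.
#' @param sources list with the frame lists the kind needs: \code{nat}
#'   (natural images) for \code{"nat"}; \code{hr} for \code{"orig"} and
#'   \code{"syn"}; \code{lr} for \code{"syn"} and \code{"res"}; optional
#'   \code{fovMask}.
#' @param patchSize output patch side in pixels.
#' @return list of \linkS4class{ImageFrame} patches.
#' @export
buildTargetDomain <- function(kind, sources, patchSize = 64L) {
  mask <- sources$fovMask
  tileAll <- function(frames, mask, size)
    do.call(c, lapply(frames, extractPatches, fovMask = mask,
                      patchSize = size))
  switch(kind,
    nat = tileAll(sources$nat, NULL, patchSize),
    orig = tileAll(sources$hr, mask, patchSize),
    syn = {
      hrP <- tileAll(sources$hr, mask, patchSize)
      lrP <- tileAll(sources$lr, mask, patchSize)
      stopifnot(length(hrP) == length(lrP))
      lapply(seq_along(hrP), function(i) {
        p <- hrP[[i]]
        attr(p, "pairedLR") <- lrP[[i]]
        p
      })
    },
    res = {
      big <- tileAll(sources$lr, mask, 4L * patchSize)
      lapply(big, function(p) {
        q <- ImageFrame(.blockMean(.fd(p), 4L), role = "HR")
        attr(q, "offset") <- attr(p, "offset")
        q
      })
    },
    stop("unknown target domain kind: '", kind,
         "' (expected nat, orig, syn or res)")
  )
}

#' Plan for a grouped train/validation/test split
#'
#' @param fractions named fractions summing to 1 for \code{train},
#'   \code{val} and \code{test}.
#' @param groupKey metadata column whose groups must not straddle subsets:
#'   \code{"video_id"} (case study CS1) or \code{"patient_id"} (CS2).
#' @param stratify balance the number of frames per clinical setting across
#'   subsets.
#' @return a validated \code{SplitPlan} list.
#' @export
splitPlan <- function(fractions = c(train = 0.70, val = 0.15, test = 0.15),
                      groupKey = c("video_id", "patient_id"),
                      stratify = TRUE) {
  groupKey <- match.arg(groupKey)
  stopifnot(abs(sum(fractions) - 1) < 1e-9, length(fractions) == 3)
  structure(list(fractions = fractions, groupKey = groupKey,
                 stratify = isTRUE(stratify)),
            class = "SplitPlan")
}

#' Group-exclusive stratified dataset split
#'
#' Randomly assigns whole groups (videos or patients, per the plan) to
#' train/validation/test so no group straddles subsets, greedily balancing
#' frame counts toward the target fractions within each clinical setting.
#' Settings with fewer than 3 groups cannot be stratified; their groups are
#' pooled and split globally (with a warning). Deterministic given the seed.
#'
#' @param metadata data.frame with columns \code{frame_id}, \code{video_id},
#'   \code{patient_id}, \code{clinical_setting}.
#' @param plan a [splitPlan()].
#' @param seed integer seed.
#' @return list of \code{frame_id} vectors: \code{train}, \code{val},
#'   \code{test}.
#' @export
splitDataset <- function(metadata, plan = splitPlan(), seed = 0L) {
  need <- c("frame_id", plan$groupKey, "clinical_setting")
  if (!all(need %in% names(metadata)))
    stop("metadata must contain columns: ", paste(need, collapse = ", "))
  grp <- as.character(metadata[[plan$groupKey]])
  setting <- if (plan$stratify) as.character(metadata$clinical_setting)
             else rep("all", nrow(metadata))

  # strata too small to stratify are pooled
  bySet <- split(grp, setting)
  small <- names(bySet)[vapply(bySet, function(g) length(unique(g)) < 3L,
                               logical(1))]
  if (length(small) && plan$stratify) {
    warning("clinical setting(s) ", paste(small, collapse = ", "),
            " have fewer than 3 groups; falling back to a global split ",
            "for them")
    setting[setting %in% small] <- ".pooled"
  }

  subsets <- c("train", "val", "test")
  alloc <- character(0)
  withSeed(seed, {
    for (s in unique(setting)) {
      rows <- which(setting == s)
      groups <- unique(grp[rows])
      groups <- sample(groups)
      sizes <- table(factor(grp[rows], levels = groups))
      target <- plan$fractions * sum(sizes)
      filled <- c(train = 0, val = 0, test = 0)
      for (g in groups) {
        deficit <- target - filled
        pick <- subsets[which.max(deficit)]
        filled[pick] <- filled[pick] + sizes[[g]]
        alloc[g] <- pick
      }
    }
  })
  res <- lapply(subsets, function(s)
    metadata$frame_id[alloc[grp] == s])
  names(res) <- subsets
  empty <- subsets[vapply(res, length, integer(1)) == 0L]
  if (length(empty))
    warning("subset(s) ", paste(empty, collapse = ", "),
            " are empty (too few groups to fill every subset)")
  res
}
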