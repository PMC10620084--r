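#' Build a region-of-interest mask
#'
#' @param include logical matrix (height x width) of pixels to keep.
#' @param excluded optional named list of logical matrices marking labeled
#'   subregions already removed from `include` (bookkeeping only).
#' @return a [RoiMask-class].
#' @export
roiMask <- function(include, excluded = list()) {
  new("RoiMask", include = include, excluded = excluded)
}

#' Remove a labeled subregion (for example the eye region) from an ROI
#'
#' The returned mask excludes the subregion's pixels; recomputing the motion
#' matrix and SVD on the reduced mask mirrors the control analysis in which
#' the eye region is removed from the face view.
#'
#' @param roi a [RoiMask-class].
#' @param subregion logical matrix of the pixels to remove.
#' @param label name under which the removed region is recorded.
#' @return a new [RoiMask-class].
#' @export
excludeSubregion <- function(roi, subregion, label = "eye") {
  if (!all(dim(subregion) == dim(roi@include)))
    stop("dimension error: subregion mask must match the ROI frame shape")
  inc <- roi@include & !subregion
  if (!any(inc))
    stop("excluding the subregion leaves no ROI pixels")
  ex <- roi@excluded
  ex[[label]] <- subregion
  roiMask(inc, ex)
}

#' Compute the motion-energy matrix of a video
#'
#' Motion energy is the absolute pixel-wise intensity difference between
#' consecutive frames, `M[p, t] = |frame[t+1][p] - frame[t][p]|`, restricted
#' to the ROI pixels. The result has one column per frame interval
#' (`n_frames - 1` columns).
#'
#' @param frames a [FrameStack-class].
#' @param roi a [RoiMask-class], or `NULL` to use every pixel.
#' @return a [MotionMatrix-class].
#' @export
computeMotionMatrix <- function(frames, roi = NULL) {
  d <- dim(frames@frames)
  nf <- d[1L]
  if (nf < 2L) stop("need at least 2 frames")
  if (is.null(roi)) roi <- roiMask(matrix(TRUE, d[2L], d[3L]))
  if (!all(dim(roi@include) == d[2:3]))
    stop("dimension error: ROI mask shape does not match the frames")
  pix <- which(roi@include)
  # flatten each frame; rows of `flat` are frames, columns pixels
  flat <- matrix(frames@frames, nrow = nf)[, pix, drop = FALSE]
  M <- t(abs(flat[-1L, , drop = FALSE] - flat[-nf, , drop = FALSE]))
  new("MotionMatrix", M = M, pixelIndex = as.integer(pix),
      frameDim = as.integer(d[2:3]), frameRate = frames@frameRate,
      view = frames@view)
}

#' Temporal-segment-wise SVD of a motion matrix
#'
#' The recording is cut into temporal segments (about one minute each), a
#' truncated SVD is computed per segment, the leading spatial components of
#' every segment are pooled (weighted by their singular values) and a second
#' SVD of the pooled matrix yields `k` orthonormal global spatial maps with
#' associated singular values. Temporal profiles are the projections of the
#' full motion matrix onto the maps. Each map is oriented so that its
#' largest-magnitude coefficient is positive, making outputs deterministic.
#'
#' @param motion a [MotionMatrix-class].
#' @param segmentLength segment length in seconds (default 60).
#' @param k number of global components requested. If `k` exceeds the
#'   feasible rank it is reduced with a warning, never silently padded.
#' @return a [MotionComponents-class].
#' @export
segmentedSvd <- function(motion, segmentLength = 60, k = 30L) {
  M <- motion@M
  npix <- nrow(M)
  ncols <- ncol(M)
  if (all(M == 0))
    stop("motion matrix is identically zero (rank 0): constant video has no movement components")
  segFrames <- max(2L, round(segmentLength * motion@frameRate))
  starts <- seq(1L, ncols, by = segFrames)
  pooled <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    idx <- starts[i]:min(starts[i] + segFrames - 1L, ncols)
    seg <- M[, idx, drop = FALSE]
    sv <- .leftSingular(seg, min(k, npix, length(idx)))
    keep <- sv$d > max(sv$d[1L], 1) * 1e-12
    if (!any(keep)) next
    pooled[[i]] <- sweep(sv$u[, keep, drop = FALSE], 2L, sv$d[keep], "*")
  }
  P <- do.call(cbind, pooled)
  if (is.null(P)) stop("no segment carried motion energy")
  feasible <- min(npix, ncol(P), ncols)
  if (k > feasible) {
    warning(sprintf("k = %d exceeds the feasible rank; reduced to %d",
                    k, feasible))
    k <- feasible
  }
  sv2 <- .leftSingular(P, k)
  U <- sv2$u[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-magnitude coefficient positive
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  new("MotionComponents", spatial = U, d = sv2$d[seq_len(k)],
      temporal = crossprod(U, M), pixelIndex = motion@pixelIndex,
      frameDim = motion@frameDim, view = motion@view)
}

# Leading left singular vectors/values of A. When A has fewer rows than
# columns the eigendecomposition of the small Gram matrix A A' is cheaper
# than a full SVD and numerically adequate for motion energy.
.leftSingular <- function(A, k) {
  k <- min(k, nrow(A), ncol(A))
  if (nrow(A) <= ncol(A)) {
    eg <- eigen(tcrossprod(A), symmetric = TRUE)
    d2 <- pmax(eg$values, 0)
    list(u = eg$vectors[, seq_len(k), drop = FALSE],
         d = sqrt(d2[seq_len(k)]))
  } else {
    sv <- svd(A, nu = k, nv = 0L)
    list(u = sv$u, d = sv$d[seq_len(k)])
  }
}

#' Project a motion matrix onto its leading components
#'
#' Returns the temporal profiles `t(spatial[, 1:topN]) %*% M`, one row per
#' component ordered by singular value. The analysis downstream keeps the
#' top 30 profiles as movement regressors by default.
#'
#' @param motion a [MotionMatrix-class].
#' @param components a [MotionComponents-class] computed from it.
#' @param topN number of leading components to project onto.
#' @return numeric matrix `topN x (n_frames - 1)`.
#' @export
projectMotion <- function(motion, components, topN = 30L) {
  k <- ncol(components@spatial)
  if (topN > k)
    stop(sprintf("bounds error: topN = %d exceeds the %d available components",
                 topN, k))
  if (nrow(motion@M) != nrow(components@spatial))
    stop("dimension error: components were computed on a different ROI")
  crossprod(components@spatial[, seq_len(topN), drop = FALSE], motion@M)
}

#' Pixel-averaged motion trace
#'
#' Averages the motion matrix over pixels, giving a single scalar motion
#' trace per frame interval (length `n_frames - 1`). This trace feeds the
#' model-free movement-epoch detection.
#'
#' @param motion a [MotionMatrix-class].
#' @return numeric vector of length `ncol(motionValues(motion))`.
#' @export
averageMotionTrace <- function(motion) {
  colMeans(motion@M)
}
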