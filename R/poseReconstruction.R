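# Inference-time 3D reconstruction: response-map decoding, robust
# per-landmark triangulation, limb-length estimation, and kinematic-chain
# refinement with limb-length and temporal-smoothness cues.

#' Decode detector response maps
#'
#' Per landmark channel, the argmax cell of the response grid is mapped back
#' to crop coordinates (cell-center convention: grid cell g covers crop
#' pixels `[g*stride, (g+1)*stride)` and decodes to its center
#' `g*stride + stride/2`), then to full-image coordinates through the crop
#' window. All-zero channels are reported missing.
#'
#' @param stack `grid x grid x (landmarks + 1)` response array (the last
#'   channel is background and is ignored).
#' @param crop The `CropWindow` the maps were computed on.
#' @param landmarks Landmark names for the channels.
#' @return Data.frame `landmark`, `x`, `y` (image pixels), `confidence`,
#'   `missing`.
#' @export
decodeResponseMaps <- function(stack, crop, landmarks = NULL) {
  if (any(stack < 0)) stop("response maps must be nonnegative")
  grid <- dim(stack)[1]
  nL <- dim(stack)[3] - 1L
  if (is.null(landmarks)) landmarks <- paste0("lm", seq_len(nL))
  stride <- crop$outputSize / grid
  out <- data.frame(landmark = landmarks, x = NA_real_, y = NA_real_,
                    confidence = 0, missing = TRUE, stringsAsFactors = FALSE)
  for (i in seq_len(nL)) {
    ch <- stack[, , i]
    mx <- max(ch)
    if (mx <= 0) next
    idx <- which(ch == mx, arr.ind = TRUE)[1, ]  # [row=y+1, col=x+1]
    cropPx <- c((idx[2] - 1) * stride + stride / 2,
                (idx[1] - 1) * stride + stride / 2)
    img <- cropToImage(crop, cropPx)
    out$x[i] <- img[1]; out$y[i] <- img[2]
    out$confidence[i] <- mx; out$missing[i] <- FALSE
  }
  out
}

# Internal: detections as arrays [frame, camera, landmark] for x, y.
detectionArrays <- function(detections, cameras) {
  rec <- detections@records
  lm <- detections@landmarkNames
  ids <- vapply(cameras, cameraId, character(1))
  nF <- max(rec$frame); nC <- length(cameras); nL <- length(lm)
  x <- array(NA_real_, c(nF, nC, nL)); y <- x
  ci <- match(rec$camera_id, ids)
  li <- match(rec$landmark, lm)
  ok <- !is.na(ci) & !is.na(li)
  idx <- cbind(rec$frame[ok], ci[ok], li[ok])
  x[idx] <- rec$x[ok]; y[idx] <- rec$y[ok]
  list(x = x, y = y, nF = nF, nC = nC, nL = nL, landmarks = lm)
}

#' Reconstruct a 3D pose sequence from multiview detections
#'
#' Every (frame, landmark) is triangulated independently with
#' [triangulateRANSAC()]; entries observed in fewer than two views, or for
#' which no consensus pair exists, are flagged invalid rather than fatal.
#'
#' @param detections A [DetectionSet-class].
#' @param cameras List of [CameraModel-class].
#' @param inlierThresholdPx RANSAC inlier gate (default 10 px).
#' @param fps Frame rate of the output sequence.
#' @return A [PoseSequence3D-class] (raw, unrefined).
#' @export
reconstructSequence <- function(detections, cameras, inlierThresholdPx = 10,
                                fps = 30) {
  da <- detectionArrays(detections, cameras)
  pos <- array(NA_real_, c(da$nF, da$nL, 3L))
  for (f in seq_len(da$nF)) {
    for (l in seq_len(da$nL)) {
      obs <- which(!is.na(da$x[f, , l]))
      if (length(obs) < 2L) next
      tri <- triangulateRANSAC(cameras[obs],
                               cbind(da$x[f, obs, l], da$y[f, obs, l]),
                               inlierThresholdPx = inlierThresholdPx)
      if (tri$valid) pos[f, l, ] <- tri$point
    }
  }
  poseSequence(pos, landmarkNames = da$landmarks, fps = fps)
}

#' Estimate limb lengths from a reconstructed sequence
#'
#' Per skeleton edge, the median over time of the distance between the two
#' endpoint landmarks, using frames where both are valid. Robust to
#' occasional spurious reconstructions.
#'
#' @param poses A [PoseSequence3D-class].
#' @param skel A [Skeleton-class].
#' @return Named numeric vector (by child landmark) of lengths in meters.
#' @export
estimateLimbLengths <- function(poses, skel) {
  edges <- skeletonEdges(skel)
  P <- poses@positions
  V <- poses@valid
  out <- numeric(nrow(edges))
  names(out) <- edges[, "child"]
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, "parent"]; b <- edges[i, "child"]
    ok <- V[, a] & V[, b]
    if (!any(ok))
      stop("edge '", a, "'-'", b, "' has no frame with both endpoints valid")
    d <- sqrt(rowSums((P[ok, a, , drop = FALSE] - P[ok, b, , drop = FALSE])^2))
    out[b] <- stats::median(d)
  }
  out
}

#' Gate raw reconstructions by limb-length plausibility
#'
#' Optional hard gate complementing the soft refinement penalty: child
#' landmarks whose instantaneous limb length deviates from the estimate by
#' more than `factor` (relative) are invalidated.
#'
#' @param poses A [PoseSequence3D-class].
#' @param skel A [Skeleton-class].
#' @param lengths Named limb lengths as from [estimateLimbLengths()].
#' @param factor Relative deviation gate (default 0.5).
#' @return A [PoseSequence3D-class] with violating entries invalidated.
#' @export
gateByLimbLength <- function(poses, skel, lengths, factor = 0.5) {
  edges <- skeletonEdges(skel)
  P <- poses@positions
  V <- poses@valid
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, "parent"]; b <- edges[i, "child"]
    ok <- V[, a] & V[, b]
    d <- sqrt(rowSums((P[, a, , drop = FALSE] - P[, b, , drop = FALSE])^2))
    bad <- ok & abs(d - lengths[b]) > factor * lengths[b]
    V[bad, b] <- FALSE
    P[bad, b, ] <- NA_real_
  }
  poseSequence(P, valid = V, landmarkNames = poses@landmarkNames, fps = poses@fps)
}

# Reprojection data for the refinement objective: per (frame, landmark), the
# observing cameras' stacked rotation/translation/intrinsics for vectorized
# evaluation.
precomputeCamBlocks <- function(cameras) {
  list(R = lapply(cameras, function(c) c@rotation),
       t = lapply(cameras, function(c) c@translation),
       f = lapply(cameras, function(c) c@focal),
       pp = lapply(cameras, function(c) c@principalPoint),
       k = lapply(cameras, function(c) c@distortion))
}

# Objective and gradient of the per-landmark refinement at one frame:
#   sum_i ||Pi_i(X) - x_i||^2 + wL (||X - Y|| - L)^2 + wT ||X - Xprev||^2
# Cameras behind which the point falls contribute nothing (their detection
# is necessarily spurious there).
refineObjective <- function(X, camIdx, obsPx, blocks, Y, L, Xprev, wL, wT) {
  val <- 0; grad <- c(0, 0, 0)
  for (j in seq_along(camIdx)) {
    i <- camIdx[j]
    Xc <- as.numeric(blocks$R[[i]] %*% X + blocks$t[[i]])
    if (Xc[3] <= 1e-9) next
    xn <- Xc[1] / Xc[3]; yn <- Xc[2] / Xc[3]
    r2 <- xn^2 + yn^2
    k <- blocks$k[[i]]
    dcoef <- 1 + k[1] * r2 + k[2] * r2^2
    f <- blocks$f[[i]]; pp <- blocks$pp[[i]]
    u <- f[1] * xn * dcoef + pp[1]
    v <- f[2] * yn * dcoef + pp[2]
    ex <- u - obsPx[j, 1]; ey <- v - obsPx[j, 2]
    val <- val + ex^2 + ey^2
    # chain rule: d(residual)/dX
    ddr2 <- k[1] + 2 * k[2] * r2
    du_dxn <- f[1] * (dcoef + xn * ddr2 * 2 * xn)
    du_dyn <- f[1] * xn * ddr2 * 2 * yn
    dv_dxn <- f[2] * yn * ddr2 * 2 * xn
    dv_dyn <- f[2] * (dcoef + yn * ddr2 * 2 * yn)
    iz <- 1 / Xc[3]
    dxn_dXc <- c(iz, 0, -xn * iz)
    dyn_dXc <- c(0, iz, -yn * iz)
    du_dXc <- du_dxn * dxn_dXc + du_dyn * dyn_dXc
    dv_dXc <- dv_dxn * dxn_dXc + dv_dyn * dyn_dXc
    gXc <- 2 * ex * du_dXc + 2 * ey * dv_dXc
    grad <- grad + as.numeric(crossprod(blocks$R[[i]], gXc))
  }
  if (!is.null(Y)) {
    dv <- X - Y
    nd <- sqrt(sum(dv^2))
    if (nd > 1e-12) {
      val <- val + wL * (nd - L)^2
      grad <- grad + wL * 2 * (nd - L) * dv / nd
    } else val <- val + wL * L^2
  }
  if (!is.null(Xprev)) {
    dv <- X - Xprev
    val <- val + wT * sum(dv^2)
    grad <- grad + wT * 2 * dv
  }
  list(value = val, grad = grad)
}

#' Dimensionally consistent refinement weights
#'
#' The refinement objective mixes squared pixel residuals with squared meter
#' residuals. Expressing the limb and temporal cues on the same footing as
#' the reprojection term requires the meters-to-pixels conversion at a
#' typical subject distance, `(focal / distance)^2`, with the limb cue
#' additionally scaled by the number of observing views (the reprojection
#' term is a sum over views) and the temporal cue down-weighted because at
#' ordinary frame rates the genuine inter-frame displacement exceeds the
#' per-frame reconstruction noise by an order of magnitude. This helper
#' returns `wL = nViews * (f / d)^2` and `wT = temporalFactor * (f / d)^2`.
#'
#' @param cameras List of [CameraModel-class].
#' @param subjectDistance Typical camera-to-subject distance (meters).
#' @param nViews Typical number of observing views (default: half the rig).
#' @param temporalFactor Down-weighting of the smoothness cue (default 0.2).
#' @return List with `wL` and `wT`.
#' @export
refineWeights <- function(cameras, subjectDistance = 2,
                          nViews = max(2L, length(cameras) %/% 2L),
                          temporalFactor = 0.2) {
  f <- mean(vapply(cameras, function(c) mean(c@focal), numeric(1)))
  s2 <- (f / subjectDistance)^2
  list(wL = nViews * s2, wT = temporalFactor * s2)
}

#' Kinematic-chain pose refinement
#'
#' Refines a raw per-landmark reconstruction by minimizing, per landmark and
#' frame, the sum of (i) squared reprojection residuals against the 2D
#' detections, (ii) a limb-length penalty `wL * (||X - Y|| - L)^2` against
#' the parent landmark, and (iii) a temporal-smoothness penalty
#' `wT * ||X - X_{t-1}||^2`. The optimization proceeds recursively along the
#' kinematic chain -- the root (neck) first, without the limb term, then each
#' child against its already-refined parent in breadth-first order -- and
#' sweeps frames forward so the smoothness term uses the already-refined
#' previous frame (dropped at the first frame). Each subproblem is solved by
#' a quasi-Newton (BFGS) method with analytic gradients from the raw
#' estimate; termination tolerance 1e-5.
#'
#' Invalid raw entries are re-initialized from the refined parent plus the
#' rest-length offset along the previous frame's limb direction when
#' available, otherwise they stay invalid.
#'
#' @param raw Raw [PoseSequence3D-class] from [reconstructSequence()].
#' @param detections The [DetectionSet-class] used for reconstruction.
#' @param cameras List of [CameraModel-class].
#' @param skel A [Skeleton-class].
#' @param limbLengths Named lengths from [estimateLimbLengths()].
#' @param wL,wT Limb and temporal weights (default 1, the plain unweighted
#'   objective; configurable because the pixel- and meter-scaled terms are
#'   dimensionally heterogeneous).
#' @param tol Relative convergence tolerance (default 1e-5).
#' @param inlierThresholdPx Detections reprojecting farther than this from
#'   the initialization are treated as spurious and excluded from the
#'   reprojection term (same gate as the RANSAC reconstruction), so gross
#'   outliers cannot drag the refinement.
#' @return A refined [PoseSequence3D-class].
#' @export
refineChain <- function(raw, detections, cameras, skel, limbLengths,
                        wL = 1, wT = 1, tol = 1e-5, inlierThresholdPx = 10) {
  da <- detectionArrays(detections, cameras)
  if (!identical(da$landmarks, raw@landmarkNames))
    stop("detections and raw poses must share the landmark vocabulary")
  blocks <- precomputeCamBlocks(cameras)
  P <- raw@positions
  V <- raw@valid
  nF <- nFrames(raw)
  order <- breadthFirstOrder(skel)
  root <- skeletonRoot(skel)
  lmIdx <- stats::setNames(seq_along(raw@landmarkNames), raw@landmarkNames)
  for (lmName in order) {
    l <- lmIdx[[lmName]]
    isRoot <- lmName == root
    parentName <- if (isRoot) NULL else skel@parents[[lmName]]
    pIdx <- if (isRoot) NA_integer_ else lmIdx[[parentName]]
    L <- if (isRoot) NA_real_ else limbLengths[[lmName]]
    for (f in seq_len(nF)) {
      camIdx <- which(!is.na(da$x[f, , l]))
      obsPx <- cbind(da$x[f, camIdx, l], da$y[f, camIdx, l])
      Y <- if (!isRoot && V[f, pIdx]) P[f, pIdx, ] else NULL
      Xprev <- if (f > 1L && V[f - 1L, l]) P[f - 1L, l, ] else NULL
      X0 <- P[f, l, ]
      if (!V[f, l]) {
        # re-initialize from the parent plus a rest-length offset along the
        # previous frame's limb direction
        if (!is.null(Y) && f > 1L && V[f - 1L, l] && V[f - 1L, pIdx]) {
          dirPrev <- P[f - 1L, l, ] - P[f - 1L, pIdx, ]
          nd <- sqrt(sum(dirPrev^2))
          if (nd > 1e-9) X0 <- Y + dirPrev / nd * L
        }
        if (any(is.na(X0))) next
        P[f, l, ] <- X0
      }
      if (length(camIdx)) {
        reproj <- reprojectionErrors(X0, cameras[camIdx], obsPx)
        good <- which(is.finite(reproj) & reproj < inlierThresholdPx)
        camIdx <- camIdx[good]
        obsPx <- obsPx[good, , drop = FALSE]
      }
      obj <- function(x) refineObjective(x, camIdx, obsPx, blocks, Y, L,
                                         Xprev, wL, wT)
      f0 <- obj(X0)$value
      fit <- tryCatch(
        stats::optim(X0, fn = function(x) obj(x)$value,
                     gr = function(x) obj(x)$grad,
                     method = "BFGS",
                     control = list(reltol = tol, maxit = 200L)),
        error = function(e) NULL)
      if (!is.null(fit) && is.finite(fit$value) && fit$value <= f0) {
        P[f, l, ] <- fit$par
      }
      V[f, l] <- TRUE
    }
  }
  poseSequence(P, valid = V, landmarkNames = raw@landmarkNames, fps = raw@fps)
}
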