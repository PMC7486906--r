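# Behavior analytics: canonical pose features, embedding/clustering, kNN
# action classification, transitions, two-animal tracking, co-occurrence,
# and proxemics.

#' Canonical body-centric pose features
#'
#' Transforms one 3D pose into the canonical coordinate system that removes
#' location, heading, and size: the neck is the origin; the canonical y-axis
#' is the gravity direction (world +z maps to canonical -y); the z-axis is
#' the projection of the neck-to-hip (spine) axis onto the horizontal plane
#' (Gram-Schmidt against y); x = y cross z; and all coordinates are divided
#' by the spine length `||neck - hip||` so the spine has unit length. The
#' neck entry (identically zero) is dropped, giving a 36-dimensional vector
#' for a 13-landmark pose, ordered by the skeleton's landmark order.
#'
#' If the spine is parallel to gravity the heading is taken from the shoulder
#' axis instead (horizontal direction perpendicular to left-right shoulders,
#' right-handed).
#'
#' @param pose `[landmarks, 3]` matrix with landmark rownames (meters).
#' @param skel A [Skeleton-class].
#' @return Numeric vector of length `3 * (landmarks - 1)`.
#' @export
canonicalize <- function(pose, skel) {
  lm <- skel@landmarkNames
  pose <- pose[lm, , drop = FALSE]
  neck <- pose[skeletonRoot(skel), ]
  hip <- pose["hip", ]
  if (any(is.na(neck)) || any(is.na(hip)))
    stop("canonicalize requires valid neck and hip landmarks")
  spine <- hip - neck
  sl <- vnorm(spine)
  if (sl < 1e-9) stop("zero-length spine: neck and hip coincide")
  yAxis <- c(0, 0, -1)  # gravity
  zH <- spine - sum(spine * yAxis) * yAxis
  if (vnorm(zH) < 1e-6 * sl) {
    # spine parallel to gravity: heading from the shoulder axis
    sh <- pose["right_shoulder", ] - pose["left_shoulder", ]
    zH <- pracmaFreeCross(c(0, 0, 1), sh)
    zH <- zH - sum(zH * yAxis) * yAxis
    if (vnorm(zH) < 1e-9)
      stop("cannot orient the canonical frame: spine and shoulders degenerate")
  }
  zAxis <- unitv(zH)
  xAxis <- pracmaFreeCross(yAxis, zAxis)
  B <- cbind(xAxis, yAxis, zAxis)
  rel <- sweep(pose, 2L, neck) %*% B / sl
  keep <- setdiff(lm, skeletonRoot(skel))
  as.numeric(t(rel[keep, , drop = FALSE]))
}

#' Canonical features for every frame of a sequence
#'
#' @param poses A [PoseSequence3D-class].
#' @param skel A [Skeleton-class].
#' @return `[frames, 3 * (landmarks - 1)]` matrix; frames with any invalid
#'   landmark yield `NA` rows.
#' @export
canonicalizeSequence <- function(poses, skel) {
  nF <- nFrames(poses)
  nOut <- 3L * (length(skel@landmarkNames) - 1L)
  out <- matrix(NA_real_, nF, nOut)
  for (f in seq_len(nF)) {
    if (!all(poses@valid[f, ])) next
    out[f, ] <- canonicalize(poseFrame(poses, f), skel)
  }
  out
}

#' Vectorized single-view 2D representation
#'
#' The raw 2D baseline: per-frame concatenation `[x1 y1 ... x13 y13]` of all
#' landmark pixels in skeleton order, deliberately without any
#' normalization, so position, viewpoint and scale leak into the feature --
#' the contrast case for the canonical 3D representation.
#'
#' @param pose2d `[landmarks, 2]` pixel matrix with landmark rownames.
#' @param skel A [Skeleton-class].
#' @return Numeric vector of length `2 * landmarks` (26 for 13 landmarks).
#' @export
vectorize2D <- function(pose2d, skel) {
  lm <- skel@landmarkNames
  pose2d <- pose2d[lm, , drop = FALSE]
  if (any(is.na(pose2d))) stop("vectorize2D requires all landmarks present")
  as.numeric(t(pose2d))
}

#' Embed pose features and group them into clusters
#'
#' Reduces the canonical features to two dimensions and groups the embedded
#' points into clusters, emulating the cluster-discovery step of behavioral
#' mapping. The embedding is a deterministic principal-component projection
#' (sign-fixed); grouping uses Gaussian-mixture model selection (BIC over
#' 1..`maxClusters` components), which behaves like density-based grouping on
#' the embedding and needs no preset cluster count. Deterministic given
#' `seed`.
#'
#' @param features `[n, d]` feature matrix (no `NA` rows), n >= 50.
#' @param seed RNG seed.
#' @param maxClusters Largest number of mixture components considered.
#' @return List with `embedding` (`[n, 2]`), `clusters` (integer vector) and
#'   `nClusters`.
#' @export
embedAndCluster <- function(features, seed = 1L, maxClusters = 9L) {
  if (anyNA(features)) stop("features must not contain NA rows")
  n <- nrow(features)
  if (n < 50L) stop("need at least 50 feature vectors to embed and cluster")
  if (nrow(unique(features)) == 1L) {
    return(list(embedding = matrix(0, n, 2L), clusters = rep(1L, n),
                nClusters = 1L))
  }
  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  emb <- pc$x[, 1:2, drop = FALSE]
  # deterministic sign convention: largest-magnitude loading positive
  for (j in 1:2) {
    ld <- pc$rotation[, j]
    if (ld[which.max(abs(ld))] < 0) emb[, j] <- -emb[, j]
  }
  fit <- withSeed(seed,
    mclust::Mclust(emb, G = seq_len(maxClusters), verbose = FALSE))
  list(embedding = emb, clusters = as.integer(fit$classification),
       nClusters = fit$G)
}

#' k-nearest-neighbor action classification
#'
#' Majority vote among the `k` nearest training features (Euclidean); ties
#' are broken by the label of the single nearest neighbor.
#'
#' @param trainFeatures `[n, d]` training matrix.
#' @param trainLabels Per-row labels (factor, character, or
#'   [ActionLabels-class]).
#' @param testFeatures `[m, d]` matrix to classify.
#' @param k Neighborhood size (odd recommended; default 15).
#' @param fps Frame rate for the returned labels.
#' @return An [ActionLabels-class] of length `m`.
#' @export
classifyActions <- function(trainFeatures, trainLabels, testFeatures,
                            k = 15L, fps = 30) {
  if (is(trainLabels, "ActionLabels")) trainLabels <- labelVector(trainLabels)
  trainLabels <- as.character(trainLabels)
  if (!nrow(trainFeatures)) stop("training set must be nonempty")
  if (k < 1L) stop("k must be >= 1")
  k <- min(k, nrow(trainFeatures))
  tr2 <- rowSums(trainFeatures^2)
  out <- character(nrow(testFeatures))
  chunk <- 512L
  for (s in seq(1L, nrow(testFeatures), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(testFeatures))
    Tm <- testFeatures[s:e, , drop = FALSE]
    d2 <- outer(rep(1, nrow(Tm)), tr2) - 2 * Tm %*% t(trainFeatures) +
      rowSums(Tm^2)
    for (i in seq_len(nrow(Tm))) {
      ord <- order(d2[i, ])[seq_len(k)]
      votes <- table(trainLabels[ord])
      top <- names(votes)[votes == max(votes)]
      out[s + i - 1L] <- if (length(top) == 1L) top else trainLabels[ord[1L]]
    }
  }
  actionLabels(out, fps = fps)
}

#' Action transition matrix
#'
#' Counts consecutive-frame label pairs and normalizes rows; rows for actions
#' never observed stay zero.
#'
#' @param labels An [ActionLabels-class] (or factor/character vector).
#' @return 6x6 row-stochastic matrix over [ACTION_LEVELS].
#' @export
transitionMatrix <- function(labels) {
  if (is(labels, "ActionLabels")) labels <- labelVector(labels)
  labels <- factor(as.character(labels), levels = ACTION_LEVELS)
  if (length(labels) < 2L) stop("need at least 2 frames")
  M <- table(from = labels[-length(labels)], to = labels[-1L])
  M <- matrix(as.numeric(M), length(ACTION_LEVELS), length(ACTION_LEVELS),
              dimnames = list(ACTION_LEVELS, ACTION_LEVELS))
  rs <- rowSums(M)
  M[rs > 0, ] <- M[rs > 0, , drop = FALSE] / rs[rs > 0]
  M
}

# --------------------------------------------------------------------------
# Two-animal tracking
# --------------------------------------------------------------------------

#' 3D candidate cloud from unlabeled per-view centroids
#'
#' With several animals in view, each camera reports centroids without
#' identities. All cross-view centroid pairs are triangulated; pairs whose
#' back-projected rays pass close to each other (gap below `maxRayGap`)
#' yield consistent 3D candidates, while mixed-identity "ghost" pairs
#' produce skew rays and are discarded. The surviving candidate cloud
#' concentrates around the true animal centers.
#'
#' @param centroids Data.frame `frame`, `camera_id`, `x`, `y` (possibly
#'   several rows per frame and camera).
#' @param cameras List of [CameraModel-class].
#' @param maxRayGap Largest allowed ray-ray distance (meters).
#' @return List (per frame) of `[k, 3]` candidate matrices.
#' @export
centroidCandidates <- function(centroids, cameras, maxRayGap = 0.05) {
  ids <- vapply(cameras, cameraId, character(1))
  frames <- sort(unique(centroids$frame))
  out <- vector("list", max(frames))
  for (f in frames) {
    sub <- centroids[centroids$frame == f, , drop = FALSE]
    m <- match(sub$camera_id, ids)
    keep <- !is.na(m)
    sub <- sub[keep, , drop = FALSE]; m <- m[keep]
    if (nrow(sub) < 2L) { out[[f]] <- matrix(numeric(0), 0L, 3L); next }
    # all cross-view pairs
    pairIdx <- utils::combn(nrow(sub), 2L)
    diffCam <- m[pairIdx[1, ]] != m[pairIdx[2, ]]
    pairIdx <- pairIdx[, diffCam, drop = FALSE]
    if (!ncol(pairIdx)) { out[[f]] <- matrix(numeric(0), 0L, 3L); next }
    cams <- lapply(seq_len(nrow(sub)), function(i) cameras[[m[i]]])
    cand <- pairwiseCandidates(cams, cbind(sub$x, sub$y),
                               pairs = cbind(pairIdx[1, ], pairIdx[2, ]))
    pts <- cand$points
    gap <- cand$gap
    ok <- is.finite(pts[, 1]) & gap < maxRayGap
    out[[f]] <- pts[ok, , drop = FALSE]
  }
  out
}

#' Track two animals through a candidate cloud
#'
#' Per frame, k-means with k = 2 splits the 3D candidate cloud into two
#' centers; identities are carried across frames by nearest-neighbor matching
#' of centers to the previous frame (the assignment is swapped iff that
#' decreases the total matching distance). Frames whose centers come closer
#' than `minSeparation` are flagged ambiguous.
#'
#' @param candidates List (per frame) of `[k, 3]` candidate matrices, as from
#'   [centroidCandidates()].
#' @param minSeparation Ambiguity radius between centers (meters).
#' @param seed RNG seed for the first frame's k-means initialization.
#' @return List with `centersA`, `centersB` (`[frames, 3]`), `ambiguous`
#'   (logical), `degenerate` (logical; frames whose cloud could not support
#'   two clusters).
#' @export
trackTwoAnimals <- function(candidates, minSeparation = 0.15, seed = 1L) {
  nF <- length(candidates)
  A <- matrix(NA_real_, nF, 3L); B <- A
  amb <- logical(nF); degen <- logical(nF)
  prev <- NULL
  for (f in seq_len(nF)) {
    pts <- candidates[[f]]
    if (is.null(pts) || nrow(pts) < 2L || nrow(unique(pts)) < 2L) {
      degen[f] <- TRUE
      next
    }
    km <- if (is.null(prev)) {
      withSeed(childSeed(seed, f), stats::kmeans(pts, centers = 2L, nstart = 10L))
    } else {
      tryCatch(suppressWarnings(stats::kmeans(pts, centers = prev)),
               error = function(e)
                 withSeed(childSeed(seed, f),
                          stats::kmeans(pts, centers = 2L, nstart = 10L)))
    }
    ctr <- km$centers
    if (!is.null(prev)) {
      straight <- vnorm(ctr[1, ] - prev[1, ]) + vnorm(ctr[2, ] - prev[2, ])
      swapped <- vnorm(ctr[2, ] - prev[1, ]) + vnorm(ctr[1, ] - prev[2, ])
      if (swapped < straight) ctr <- ctr[c(2L, 1L), ]
    }
    A[f, ] <- ctr[1, ]; B[f, ] <- ctr[2, ]
    amb[f] <- vnorm(ctr[1, ] - ctr[2, ]) < minSeparation
    prev <- ctr
  }
  list(centersA = A, centersB = B, ambiguous = amb, degenerate = degen)
}

#' Action co-occurrence of two animals
#'
#' Joint frame counts of (action of A, action of B), with a log display
#' transform attached for plotting.
#'
#' @param labelsA,labelsB [ActionLabels-class] (or vectors) of equal length.
#' @return 6x6 count matrix with attribute `log` = `log1p(counts)`.
#' @export
cooccurrence <- function(labelsA, labelsB) {
  if (is(labelsA, "ActionLabels")) labelsA <- labelVector(labelsA)
  if (is(labelsB, "ActionLabels")) labelsB <- labelVector(labelsB)
  if (length(labelsA) != length(labelsB))
    stop("label streams must have equal length")
  la <- factor(as.character(labelsA), levels = ACTION_LEVELS)
  lb <- factor(as.character(labelsB), levels = ACTION_LEVELS)
  M <- table(A = la, B = lb)
  M <- matrix(as.numeric(M), length(ACTION_LEVELS), length(ACTION_LEVELS),
              dimnames = list(ACTION_LEVELS, ACTION_LEVELS))
  attr(M, "log") <- log1p(M)
  M
}

#' Horizontal facing direction of a pose
#'
#' The horizontal projection of the neck-to-nose vector; if degenerate, the
#' horizontal direction perpendicular to the shoulder axis (right-handed) is
#' used.
#'
#' @param pose `[landmarks, 3]` matrix with landmark rownames.
#' @return Unit length-2 vector (x, y), or `NA`s if not computable.
#' @export
facingDirection <- function(pose) {
  v <- pose["nose", 1:2] - pose["neck", 1:2]
  if (all(is.finite(v)) && vnorm(v) > 1e-9) return(unitv(v))
  sh <- pose["right_shoulder", ] - pose["left_shoulder", ]
  if (any(!is.finite(sh))) return(c(NA_real_, NA_real_))
  f3 <- pracmaFreeCross(c(0, 0, 1), sh)
  if (vnorm(f3[1:2]) < 1e-9) return(c(NA_real_, NA_real_))
  unitv(f3[1:2])
}

#' Proxemics: body-centric polar histogram of a conspecific's position
#'
#' Per frame, the second animal's neck is expressed in the first animal's
#' body-centric frame -- origin at A's neck, 0 degrees along A's facing
#' direction, angles in the horizontal plane, counter-clockwise (A's left)
#' positive -- and the (distance, bearing) pairs are histogrammed on the
#' given polar grid. The histogram is normalized to total mass 1.
#'
#' @param posesA,posesB [PoseSequence3D-class] with aligned frames.
#' @param rEdges Radial bin edges (meters).
#' @param thetaEdges Angular bin edges in degrees within [-180, 180].
#' @return A `PolarHistogram` (classed list: `rEdges`, `thetaEdges`, `mass`,
#'   `nUsed`, `nSkipped`).
#' @export
proxemics <- function(posesA, posesB,
                      rEdges = seq(0, 3, by = 0.25),
                      thetaEdges = seq(-180, 180, by = 30)) {
  nF <- min(nFrames(posesA), nFrames(posesB))
  mass <- matrix(0, length(rEdges) - 1L, length(thetaEdges) - 1L)
  used <- 0L; skipped <- 0L
  for (f in seq_len(nF)) {
    pa <- poseFrame(posesA, f); pb <- poseFrame(posesB, f)
    if (any(is.na(pa["neck", ])) || any(is.na(pb["neck", ]))) {
      skipped <- skipped + 1L; next
    }
    fdir <- facingDirection(pa)
    if (any(is.na(fdir))) { skipped <- skipped + 1L; next }
    rel <- pb["neck", 1:2] - pa["neck", 1:2]
    r <- vnorm(rel)
    th <- signedAngleDeg(fdir, rel)
    ri <- findInterval(r, rEdges, rightmost.closed = TRUE)
    ti <- findInterval(th, thetaEdges, rightmost.closed = TRUE)
    if (ri >= 1 && ri <= nrow(mass) && ti >= 1 && ti <= ncol(mass)) {
      mass[ri, ti] <- mass[ri, ti] + 1
      used <- used + 1L
    } else skipped <- skipped + 1L
  }
  if (used > 0L) mass <- mass / sum(mass)
  structure(list(rEdges = rEdges, thetaEdges = thetaEdges, mass = mass,
                 nUsed = used, nSkipped = skipped),
            class = "PolarHistogram")
}
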