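# Camera models, projection/distortion, and the three triangulators that
# every other module builds on.

#' Project world points into a camera
#'
#' Pinhole projection with two-term radial distortion: a world point is mapped
#' to camera coordinates, perspective-divided, distorted, and scaled by the
#' intrinsics. Points must lie in front of the camera.
#'
#' @param camera A [CameraModel-class].
#' @param points Numeric length-3 vector or `[n, 3]` matrix (meters).
#' @param clipBehind If `TRUE`, points with non-positive depth yield `NA`
#'   pixels instead of an error (used by the emulators).
#' @return `[n, 2]` matrix of pixel coordinates.
#' @examples
#' cam <- cameraModel("c1", 625, c(640, 512))
#' projectPoints(cam, c(0, 0, 2))   # principal point
#' @export
projectPoints <- function(camera, points, clipBehind = FALSE) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  Xc <- points %*% t(camera@rotation) +
    matrix(camera@translation, nrow(points), 3L, byrow = TRUE)
  z <- Xc[, 3]
  behind <- z <= 1e-12
  if (any(behind) && !clipBehind)
    stop("behind-camera: point has non-positive depth in the camera frame")
  z[behind] <- NA_real_
  xn <- Xc[, 1] / z
  yn <- Xc[, 2] / z
  r2 <- xn^2 + yn^2
  k <- camera@distortion
  d <- 1 + k[1] * r2 + k[2] * r2^2
  px <- camera@focal[1] * xn * d + camera@principalPoint[1]
  py <- camera@focal[2] * yn * d + camera@principalPoint[2]
  cbind(x = px, y = py)
}

#' Depth of world points in the camera frame
#'
#' @inheritParams projectPoints
#' @return Numeric vector of depths (meters); positive means in front.
#' @export
pointDepth <- function(camera, points) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  as.numeric(points %*% camera@rotation[3, ] + camera@translation[3])
}

#' Remove lens distortion from pixel observations
#'
#' Inverts the two-term radial model by Newton iteration on the radial
#' magnification, returning normalized (unit focal length) image coordinates.
#' Accurate to well below 1e-9 px for |k1|, |k2| <= 0.3 over the image domain.
#'
#' @param camera A [CameraModel-class].
#' @param pixels `[n, 2]` pixel matrix (or length-2 vector).
#' @return `[n, 2]` matrix of undistorted normalized coordinates.
#' @export
undistortPixels <- function(camera, pixels) {
  if (is.null(dim(pixels))) pixels <- matrix(pixels, nrow = 1L)
  xd <- (pixels[, 1] - camera@principalPoint[1]) / camera@focal[1]
  yd <- (pixels[, 2] - camera@principalPoint[2]) / camera@focal[2]
  k <- camera@distortion
  if (all(k == 0)) return(cbind(x = xd, y = yd))
  rd <- sqrt(xd^2 + yd^2)
  ru <- rd  # initial guess
  for (i in 1:50) {
    f <- ru * (1 + k[1] * ru^2 + k[2] * ru^4) - rd
    fp <- 1 + 3 * k[1] * ru^2 + 5 * k[2] * ru^4
    step <- f / fp
    ru <- ru - step
    if (max(abs(step), na.rm = TRUE) < 1e-14) break
  }
  scale <- ifelse(rd > 0, ru / rd, 1)
  cbind(x = xd * scale, y = yd * scale)
}

#' Back-project pixels to world rays
#'
#' @param camera A [CameraModel-class].
#' @param pixels `[n, 2]` pixel matrix.
#' @return List with `origin` (camera center, length-3) and `directions`
#'   (`[n, 3]` unit vectors in world coordinates).
#' @export
pixelRays <- function(camera, pixels) {
  xy <- undistortPixels(camera, pixels)
  dirs <- cbind(xy[, 1], xy[, 2], 1) %*% camera@rotation  # R^T * [x y 1]
  dirs <- dirs / sqrt(rowSums(dirs^2))
  list(origin = cameraCenter(camera), directions = dirs)
}

# Stack the homogeneous DLT design matrix for one point from per-camera
# normalized observations. obs: list of list(camera=, xy=normalized c(x, y)).
dltDesign <- function(cams, xy) {
  A <- matrix(0, 2L * length(cams), 4L)
  for (i in seq_along(cams)) {
    P <- cbind(cams[[i]]@rotation, cams[[i]]@translation)
    A[2L * i - 1L, ] <- xy[i, 1] * P[3, ] - P[1, ]
    A[2L * i, ] <- xy[i, 2] * P[3, ] - P[2, ]
  }
  A
}

#' Triangulate a 3D point by the direct linear transform
#'
#' Observations are undistorted to normalized coordinates, the homogeneous
#' linear system is stacked, and the least-squares solution is taken from the
#' SVD. On noiseless consistent input the generating point is recovered.
#'
#' @param cameras List of [CameraModel-class] objects.
#' @param pixels `[n, 2]` matrix of pixel observations, one row per camera.
#' @param minViews Minimum number of views required (default 2).
#' @param conditionMax Degenerate-geometry threshold on the ratio of the first
#'   to third singular value of the design matrix.
#' @return Numeric length-3 world point (meters).
#' @examples
#' cams <- list(cameraModel("a", 625, c(640, 512)),
#'              cameraModel("b", 625, c(640, 512),
#'                          translation = c(-0.35, 0, 0)))
#' p <- c(0, 0.5, 3)
#' px <- rbind(projectPoints(cams[[1]], p), projectPoints(cams[[2]], p))
#' triangulateDLT(cams, px)
#' @export
triangulateDLT <- function(cameras, pixels, minViews = 2L, conditionMax = 1e8) {
  if (is.null(dim(pixels))) pixels <- matrix(pixels, ncol = 2L)
  n <- length(cameras)
  if (nrow(pixels) != n) stop("pixels must have one row per camera")
  if (n < minViews)
    stop("insufficient-views: need at least ", minViews, " observations")
  xy <- matrix(0, n, 2L)
  for (i in seq_len(n)) xy[i, ] <- undistortPixels(cameras[[i]], pixels[i, ])
  A <- dltDesign(cameras, xy)
  sv <- svd(A)
  if (sv$d[1] / max(sv$d[3], .Machine$double.xmin) > conditionMax)
    stop("degenerate-geometry: near-parallel rays (design matrix ill-conditioned)")
  X <- sv$v[, 4]
  if (abs(X[4]) < 1e-14)
    stop("degenerate-geometry: point at infinity")
  X[1:3] / X[4]
}

#' Mean reprojection error of a world point
#'
#' @param point Length-3 world point.
#' @param cameras List of [CameraModel-class].
#' @param pixels `[n, 2]` observed pixels.
#' @return Mean Euclidean pixel error across views (behind-camera views count
#'   as infinite error).
#' @export
meanReprojectionError <- function(point, cameras, pixels) {
  mean(reprojectionErrors(point, cameras, pixels))
}

#' @describeIn meanReprojectionError Per-view reprojection errors (pixels).
#' @export
reprojectionErrors <- function(point, cameras, pixels) {
  if (is.null(dim(pixels))) pixels <- matrix(pixels, ncol = 2L)
  vapply(seq_along(cameras), function(i) {
    if (pointDepth(cameras[[i]], point) <= 0) return(Inf)
    pr <- projectPoints(cameras[[i]], point)
    sqrt(sum((pr - pixels[i, ])^2))
  }, numeric(1))
}

# Closed-form two-view triangulation for all camera pairs: midpoint of the
# common perpendicular of the two back-projected rays. Vectorized over pairs.
# Returns a [nPairs, 3] matrix (NA rows for near-parallel rays) plus the pair
# index matrix.
pairwiseCandidates <- function(cameras, pixels, pairs = NULL) {
  n <- length(cameras)
  origins <- t(vapply(cameras, cameraCenter, numeric(3)))
  dirs <- matrix(0, n, 3L)
  for (i in seq_len(n))
    dirs[i, ] <- pixelRays(cameras[[i]], pixels[i, , drop = FALSE])$directions
  if (is.null(pairs)) {
    idx <- utils::combn(n, 2L)
    pairs <- cbind(idx[1, ], idx[2, ])
  }
  o1 <- origins[pairs[, 1], , drop = FALSE]; o2 <- origins[pairs[, 2], , drop = FALSE]
  d1 <- dirs[pairs[, 1], , drop = FALSE];    d2 <- dirs[pairs[, 2], , drop = FALSE]
  w <- o1 - o2
  b <- rowSums(d1 * d2)
  dd <- rowSums(d1 * w)
  ee <- rowSums(d2 * w)
  denom <- 1 - b^2
  s <- (b * ee - dd) / denom          # parameter along ray 1
  t2 <- (ee - b * dd) / denom         # parameter along ray 2
  bad <- abs(denom) < 1e-12
  s[bad] <- NA_real_; t2[bad] <- NA_real_
  q1 <- o1 + d1 * s
  q2 <- o2 + d2 * t2
  mid <- (q1 + q2) / 2
  gap <- sqrt(rowSums((q1 - q2)^2))
  list(points = mid, pairs = pairs, gap = gap)
}

#' Robust triangulation by random sample consensus
#'
#' Candidate 3D points are generated by two-view triangulation of camera
#' pairs and validated by reprojecting onto the remaining views; the candidate
#' with the most inliers (reprojection error below `inlierThresholdPx`) wins
#' and the final point is the DLT solution over its inliers. For up to 62
#' observations every camera pair is tried exhaustively (no sampling
#' variance); beyond that, `nIterations` random pairs are drawn from a seeded
#' RNG.
#'
#' @param cameras List of [CameraModel-class].
#' @param pixels `[n, 2]` observed pixels.
#' @param inlierThresholdPx Inlier gate on reprojection error (default 10 px,
#'   mirroring the annotation-verification gate).
#' @param nIterations Number of random pairs when not exhaustive.
#' @param seed RNG seed for the sampled regime.
#' @param exhaustiveMax Largest n for which all pairs are enumerated.
#' @return List with `point` (length-3 or `NA` if invalid), `valid`,
#'   `inlierCameraIds`, `meanReprojectionError` (over inliers, pixels).
#' @export
triangulateRANSAC <- function(cameras, pixels, inlierThresholdPx = 10,
                              nIterations = 500L, seed = NULL,
                              exhaustiveMax = 62L) {
  if (is.null(dim(pixels))) pixels <- matrix(pixels, ncol = 2L)
  n <- length(cameras)
  if (n < 2L) stop("insufficient-views: RANSAC needs at least 2 observations")
  invalid <- list(point = rep(NA_real_, 3), valid = FALSE,
                  inlierCameraIds = character(), meanReprojectionError = NA_real_)
  pairs <- NULL
  if (n > exhaustiveMax) {
    pairs <- withSeed(seed, {
      cbind(sample.int(n, nIterations, replace = TRUE),
            sample.int(n, nIterations, replace = TRUE))
    })
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  }
  cand <- pairwiseCandidates(cameras, pixels, pairs)
  pts <- cand$points
  keep <- is.finite(pts[, 1])
  pts <- pts[keep, , drop = FALSE]
  if (!nrow(pts)) return(invalid)

  # reprojection errors of every candidate in every camera, vectorized per cam
  errs <- matrix(Inf, nrow(pts), n)
  for (i in seq_len(n)) {
    depth <- pointDepth(cameras[[i]], pts)
    pr <- projectPoints(cameras[[i]], pts, clipBehind = TRUE)
    e <- sqrt((pr[, 1] - pixels[i, 1])^2 + (pr[, 2] - pixels[i, 2])^2)
    e[depth <= 0 | !is.finite(e)] <- Inf
    errs[, i] <- e
  }
  inl <- errs < inlierThresholdPx
  counts <- rowSums(inl)
  if (max(counts) < 2L) return(invalid)
  best <- which(counts == max(counts))
  if (length(best) > 1L) {
    # tie-break on mean inlier error
    me <- vapply(best, function(j) mean(errs[j, inl[j, ]]), numeric(1))
    best <- best[which.min(me)]
  }
  sel <- which(inl[best, ])
  point <- triangulateDLT(cameras[sel], pixels[sel, , drop = FALSE])
  ids <- vapply(cameras[sel], cameraId, character(1))
  mre <- mean(reprojectionErrors(point, cameras[sel], pixels[sel, , drop = FALSE]))
  list(point = point, valid = TRUE, inlierCameraIds = ids,
       meanReprojectionError = mre)
}

#' Mean-shift triangulation
#'
#' Triangulates every camera pair and mode-seeks over the resulting 3D
#' candidate cloud with a Gaussian kernel, returning the densest mode. Robust
#' to a minority of outlier views without an explicit inlier gate.
#'
#' @param cameras List of [CameraModel-class].
#' @param pixels `[n, 2]` observed pixels.
#' @param bandwidth Gaussian kernel bandwidth in meters (default 0.05).
#' @param tol Convergence tolerance on the mode shift (meters).
#' @param maxIter Iteration cap.
#' @return Length-3 world point (meters).
#' @export
triangulateMeanShift <- function(cameras, pixels, bandwidth = 0.05,
                                 tol = 1e-9, maxIter = 500L) {
  if (is.null(dim(pixels))) pixels <- matrix(pixels, ncol = 2L)
  if (length(cameras) < 2L)
    stop("insufficient-views: need at least 2 observations")
  cand <- pairwiseCandidates(cameras, pixels)
  pts <- cand$points[is.finite(cand$points[, 1]), , drop = FALSE]
  if (!nrow(pts)) stop("degenerate-geometry: no finite pairwise candidates")
  h2 <- bandwidth^2
  dens <- function(m) {
    d2 <- rowSums((pts - matrix(m, nrow(pts), 3L, byrow = TRUE))^2)
    sum(exp(-d2 / (2 * h2)))
  }
  m <- pts[which.max(apply(pts, 1, dens)), ]
  for (it in seq_len(maxIter)) {
    d2 <- rowSums((pts - matrix(m, nrow(pts), 3L, byrow = TRUE))^2)
    w <- exp(-d2 / (2 * h2))
    mNew <- colSums(pts * w) / sum(w)
    if (vnorm(mNew - m) < tol) return(mNew)
    m <- mNew
  }
  m
}

#' Viewing-angle difference between two vantage points
#'
#' The angle subtended at a subject by two cameras separated by `baseline`,
#' with the subject `distance` away from both (isoceles configuration):
#' `2 * asin(baseline / (2 * distance))`, in degrees.
#'
#' @param baseline Camera separation (meters).
#' @param distance Subject distance (meters).
#' @return Angle in degrees.
#' @export
viewingAngleDeg <- function(baseline, distance) {
  2 * asin(baseline / (2 * distance)) * 180 / pi
}

#' Adjacent-camera baselines of a rig
#'
#' Distances between consecutive same-level cameras (ordered by azimuth), a
#' proxy for the rig's stereo conditioning.
#'
#' @param cameras List of [CameraModel-class] from [makeRig()].
#' @return Numeric vector of baselines (meters).
#' @export
adjacentBaselines <- function(cameras) {
  ctr <- t(vapply(cameras, cameraCenter, numeric(3)))
  lev <- round(ctr[, 3], 6)
  out <- numeric(0)
  for (z in unique(lev)) {
    sub <- ctr[lev == z, , drop = FALSE]
    if (nrow(sub) < 2L) next
    az <- atan2(sub[, 2], sub[, 1])
    sub <- sub[order(az), , drop = FALSE]
    nxt <- rbind(sub[-1, , drop = FALSE], sub[1, , drop = FALSE])
    out <- c(out, sqrt(rowSums((sub - nxt)^2)))
  }
  out
}

# ---------------------------------------------------------------------------
# Calibration JSON
# ---------------------------------------------------------------------------

#' Read / write calibration JSON
#'
#' The interchange format is a JSON list of cameras, each
#' `{"camera_id", "K": 3x3, "dist": [k1,k2], "R": 3x3 row-major, "t": [tx,ty,tz],
#' "image_size": [w,h]}`. Invariants are validated on load.
#'
#' @param path File path.
#' @return `readCalibration` returns a list of [CameraModel-class].
#' @export
readCalibration <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(js, function(c0) {
    K <- do.call(rbind, lapply(c0$K, unlist))
    cameraModel(c0$camera_id, focal = c(K[1, 1], K[2, 2]),
                principalPoint = c(K[1, 3], K[2, 3]),
                distortion = unlist(c0$dist),
                rotation = do.call(rbind, lapply(c0$R, unlist)),
                translation = unlist(c0$t),
                imageSize = unlist(c0$image_size))
  })
}

#' @describeIn readCalibration Write a camera list to calibration JSON.
#' @param cameras List of [CameraModel-class].
#' @export
writeCalibration <- function(cameras, path) {
  js <- lapply(cameras, function(cm) {
    K <- rbind(c(cm@focal[1], 0, cm@principalPoint[1]),
               c(0, cm@focal[2], cm@principalPoint[2]),
               c(0, 0, 1))
    list(camera_id = cm@cameraId,
         K = apply(K, 1, as.list, simplify = FALSE),
         dist = cm@distortion,
         R = apply(cm@rotation, 1, as.list, simplify = FALSE),
         t = cm@translation,
         image_size = cm@imageSize)
  })
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
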