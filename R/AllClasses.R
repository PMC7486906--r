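#' @import methods
NULL

#' Action vocabulary
#'
#' The fixed set of action labels recognised throughout the package.
#' @export
ACTION_LEVELS <- c("sit", "stand", "walk", "climb", "climb_supine", "jump")

# ---------------------------------------------------------------------------
# CameraModel
# ---------------------------------------------------------------------------

#' Calibrated pinhole camera
#'
#' One calibrated camera: pinhole intrinsics, two-term radial (Brown)
#' distortion, and a rigid world-to-camera pose. The camera frame has z
#' forward, x right, y down; pixels are 0-based with coordinates referring to
#' pixel centers. World units are meters.
#'
#' @slot cameraId Character identifier.
#' @slot focal Numeric length-2, focal lengths (fx, fy) in pixels.
#' @slot principalPoint Numeric length-2, (cx, cy) in pixels.
#' @slot distortion Numeric length-2, radial coefficients (k1, k2).
#' @slot rotation 3x3 world-to-camera rotation matrix.
#' @slot translation Numeric length-3 translation (meters); a world point X
#'   maps to camera coordinates `rotation %*% X + translation`.
#' @slot imageSize Integer length-2, (width, height) in pixels.
#'
#' @seealso [cameraModel()], [projectPoints()]
#' @export
setClass("CameraModel", representation(
  cameraId = "character",
  focal = "numeric",
  principalPoint = "numeric",
  distortion = "numeric",
  rotation = "matrix",
  translation = "numeric",
  imageSize = "integer"
))

setValidity("CameraModel", function(object) {
  msg <- character()
  if (length(object@cameraId) != 1L || !nzchar(object@cameraId))
    msg <- c(msg, "cameraId must be a single non-empty string")
  if (length(object@focal) != 2L || any(object@focal <= 0))
    msg <- c(msg, "focal lengths must be two positive numbers")
  if (length(object@principalPoint) != 2L)
    msg <- c(msg, "principalPoint must have length 2")
  if (length(object@distortion) != 2L)
    msg <- c(msg, "distortion must be (k1, k2)")
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L)))
    msg <- c(msg, "rotation must be 3x3")
  else {
    if (max(abs(crossprod(R) - diag(3))) >= 1e-9)
      msg <- c(msg, "rotation must be orthonormal (||R'R - I|| < 1e-9)")
    if (abs(det(R) - 1) >= 1e-9)
      msg <- c(msg, "rotation must have determinant +1")
  }
  if (length(object@translation) != 3L)
    msg <- c(msg, "translation must have length 3")
  if (length(object@imageSize) != 2L || any(object@imageSize <= 0L))
    msg <- c(msg, "imageSize must be two positive integers")
  if (length(msg)) msg else TRUE
})

#' Construct a CameraModel
#'
#' @param cameraId Character identifier.
#' @param focal Focal lengths (fx, fy) in pixels (scalar recycled).
#' @param principalPoint Principal point (cx, cy) in pixels.
#' @param distortion Radial coefficients (k1, k2); default no distortion.
#' @param rotation 3x3 world-to-camera rotation.
#' @param translation Length-3 translation in meters.
#' @param imageSize Image (width, height) in pixels.
#' @return A [CameraModel-class] object.
#' @examples
#' cam <- cameraModel("c1", focal = 625, principalPoint = c(640, 512),
#'                    imageSize = c(1280, 1024))
#' projectPoints(cam, c(0, 0, 2))
#' @export
cameraModel <- function(cameraId, focal, principalPoint,
                        distortion = c(0, 0),
                        rotation = diag(3), translation = c(0, 0, 0),
                        imageSize = c(1280L, 1024L)) {
  if (length(focal) == 1L) focal <- rep(focal, 2L)
  new("CameraModel", cameraId = as.character(cameraId),
      focal = as.numeric(focal), principalPoint = as.numeric(principalPoint),
      distortion = as.numeric(distortion),
      rotation = matrix(as.numeric(rotation), 3L, 3L),
      translation = as.numeric(translation),
      imageSize = as.integer(imageSize))
}

#' @describeIn cameraModel Optical center (world coordinates, meters).
#' @param camera A [CameraModel-class].
#' @export
cameraCenter <- function(camera) {
  as.numeric(-crossprod(camera@rotation, camera@translation))
}

#' @export
setMethod("show", "CameraModel", function(object) {
  cat(sprintf("CameraModel '%s': f=(%.1f, %.1f) px, c=(%.1f, %.1f), image %dx%d\n",
              object@cameraId, object@focal[1], object@focal[2],
              object@principalPoint[1], object@principalPoint[2],
              object@imageSize[1], object@imageSize[2]))
  ctr <- cameraCenter(object)
  cat(sprintf("  center (%.3f, %.3f, %.3f) m, distortion k=(%g, %g)\n",
              ctr[1], ctr[2], ctr[3], object@distortion[1], object@distortion[2]))
})

#' @describeIn cameraModel Camera identifier accessor.
#' @export
cameraId <- function(camera) camera@cameraId

# ---------------------------------------------------------------------------
# Skeleton
# ---------------------------------------------------------------------------

#' Articulated skeleton definition
#'
#' The named landmark set, the kinematic tree (rooted at the neck), rest limb
#' lengths per edge, and bilateral left/right landmark pairs.
#'
#' @slot landmarkNames Ordered character vector of landmark names.
#' @slot parents Named character vector mapping each landmark to its parent;
#'   the root maps to `NA`.
#' @slot restLengths Named numeric vector of rest limb lengths (meters), named
#'   by the child landmark of each edge.
#' @slot bilateralPairs Two-column character matrix of (left, right) pairs.
#'
#' @seealso [skeleton()], [defaultSkeleton()]
#' @export
setClass("Skeleton", representation(
  landmarkNames = "character",
  parents = "character",
  restLengths = "numeric",
  bilateralPairs = "matrix"
))

setValidity("Skeleton", function(object) {
  msg <- character()
  lm <- object@landmarkNames
  if (anyDuplicated(lm)) msg <- c(msg, "landmark names must be unique")
  p <- object@parents
  if (!setequal(names(p), lm)) msg <- c(msg, "parents must be named by every landmark")
  roots <- names(p)[is.na(p)]
  if (length(roots) != 1L) msg <- c(msg, "exactly one root landmark required")
  nonroot <- setdiff(lm, roots)
  if (!all(p[nonroot] %in% lm)) msg <- c(msg, "every parent must be a landmark")
  # tree check: walking up from every node must terminate at the root
  for (l in nonroot) {
    seen <- character(); cur <- l
    while (!is.na(p[[cur]])) {
      if (cur %in% seen) { msg <- c(msg, "parent map contains a cycle"); break }
      seen <- c(seen, cur); cur <- p[[cur]]
    }
  }
  if (!setequal(names(object@restLengths), nonroot))
    msg <- c(msg, "restLengths must be named by every non-root landmark")
  else if (any(object@restLengths <= 0))
    msg <- c(msg, "rest lengths must be positive")
  bp <- object@bilateralPairs
  if (ncol(bp) != 2L) msg <- c(msg, "bilateralPairs must have two columns")
  else {
    if (!all(bp %in% lm)) msg <- c(msg, "bilateral pairs must name landmarks")
    if (anyDuplicated(as.vector(bp))) msg <- c(msg, "bilateral pairs must be disjoint")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Skeleton
#'
#' @param landmarkNames Ordered landmark names.
#' @param parents Named character vector landmark -> parent (`NA` for the root).
#' @param restLengths Named numeric vector (by child landmark) of limb rest
#'   lengths in meters.
#' @param bilateralPairs Two-column character matrix of (left, right) names.
#' @return A [Skeleton-class] object.
#' @export
skeleton <- function(landmarkNames, parents, restLengths, bilateralPairs) {
  new("Skeleton", landmarkNames = landmarkNames, parents = parents,
      restLengths = restLengths,
      bilateralPairs = matrix(as.character(bilateralPairs), ncol = 2L))
}

#' @describeIn skeleton Landmark names accessor.
#' @param x A [Skeleton-class].
#' @export
landmarkNames <- function(x) x@landmarkNames

#' @describeIn skeleton Root landmark name.
#' @export
skeletonRoot <- function(x) names(x@parents)[is.na(x@parents)]

#' @describeIn skeleton Two-column matrix of (parent, child) edges.
#' @export
skeletonEdges <- function(x) {
  ch <- names(x@parents)[!is.na(x@parents)]
  cbind(parent = unname(x@parents[ch]), child = ch)
}

#' @describeIn skeleton Landmarks in breadth-first order from the root.
#' @export
breadthFirstOrder <- function(x) {
  root <- skeletonRoot(x)
  out <- root
  frontier <- root
  while (length(frontier)) {
    kids <- names(x@parents)[!is.na(x@parents) & x@parents %in% frontier]
    kids <- kids[order(match(kids, x@landmarkNames))]
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' @export
setMethod("show", "Skeleton", function(object) {
  cat(sprintf("Skeleton: %d landmarks, root '%s', %d bilateral pairs\n",
              length(object@landmarkNames), skeletonRoot(object),
              nrow(object@bilateralPairs)))
  cat(" ", paste(object@landmarkNames, collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# DetectionSet
# ---------------------------------------------------------------------------

#' Per-view 2D landmark observations
#'
#' A table of 2D pixel observations, one row per (frame, camera, landmark),
#' with a confidence in [0, 1] and a provenance tag (`"detector"`, `"human"`,
#' or `"propagated"`).
#'
#' @slot records A data.frame with columns `frame` (integer, 1-based),
#'   `camera_id`, `landmark`, `x`, `y` (pixels), `confidence`, `source`.
#' @slot landmarkNames Ordered landmark vocabulary.
#'
#' @seealso [detectionSet()], [emulateDetections()]
#' @export
setClass("DetectionSet", representation(
  records = "data.frame",
  landmarkNames = "character"
))

setValidity("DetectionSet", function(object) {
  msg <- character()
  need <- c("frame", "camera_id", "landmark", "x", "y", "confidence", "source")
  if (!all(need %in% names(object@records)))
    msg <- c(msg, paste("records must contain columns:", paste(need, collapse = ", ")))
  else {
    r <- object@records
    if (nrow(r)) {
      if (any(!is.finite(r$x)) || any(!is.finite(r$y)))
        msg <- c(msg, "pixel coordinates must be finite")
      if (any(r$confidence < 0 | r$confidence > 1))
        msg <- c(msg, "confidence must lie in [0, 1]")
      if (!all(r$landmark %in% object@landmarkNames))
        msg <- c(msg, "landmarks must belong to the landmark vocabulary")
      if (anyDuplicated(r[c("frame", "camera_id", "landmark")]))
        msg <- c(msg, "(frame, camera_id, landmark) must be unique")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DetectionSet
#'
#' @param records Data.frame with columns `frame`, `camera_id`, `landmark`,
#'   `x`, `y`, `confidence`, `source`.
#' @param landmarkNames Landmark vocabulary (defaults to the landmarks present).
#' @return A [DetectionSet-class].
#' @export
detectionSet <- function(records, landmarkNames = unique(records$landmark)) {
  records$frame <- as.integer(records$frame)
  records$camera_id <- as.character(records$camera_id)
  records$landmark <- as.character(records$landmark)
  if (is.null(records$confidence)) records$confidence <- 1
  if (is.null(records$source)) records$source <- "detector"
  rownames(records) <- NULL
  new("DetectionSet", records = records, landmarkNames = landmarkNames)
}

#' @describeIn detectionSet Records accessor.
#' @param x A [DetectionSet-class].
#' @export
detectionRecords <- function(x) x@records

#' @export
setMethod("show", "DetectionSet", function(object) {
  r <- object@records
  cat(sprintf("DetectionSet: %d observations, %d frames, %d cameras, %d landmarks\n",
              nrow(r), length(unique(r$frame)), length(unique(r$camera_id)),
              length(object@landmarkNames)))
  if (nrow(r)) {
    src <- table(r$source)
    cat("  sources:", paste(sprintf("%s=%d", names(src), src), collapse = ", "), "\n")
  }
})

# ---------------------------------------------------------------------------
# PoseSequence3D
# ---------------------------------------------------------------------------

#' 3D pose sequence
#'
#' Per-frame, per-landmark 3D positions in meters with validity flags.
#'
#' @slot positions Numeric array `[frames, landmarks, 3]` (meters); entries for
#'   invalid (frame, landmark) pairs are `NA`.
#' @slot valid Logical matrix `[frames, landmarks]`.
#' @slot landmarkNames Ordered landmark names (array dimnames agree).
#' @slot fps Frame rate in Hz.
#'
#' @seealso [poseSequence()], [reconstructSequence()]
#' @export
setClass("PoseSequence3D", representation(
  positions = "array",
  valid = "matrix",
  landmarkNames = "character",
  fps = "numeric"
))

setValidity("PoseSequence3D", function(object) {
  msg <- character()
  d <- dim(object@positions)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "positions must be a [frames, landmarks, 3] array")
  else {
    if (!all(dim(object@valid) == d[1:2]))
      msg <- c(msg, "valid must be [frames, landmarks]")
    if (d[2] != length(object@landmarkNames))
      msg <- c(msg, "landmark dimension must match landmarkNames")
    ok <- apply(is.finite(object@positions), c(1, 2), all)
    if (any(object@valid & !ok))
      msg <- c(msg, "valid entries must carry finite positions")
  }
  if (length(object@fps) != 1L || object@fps <= 0)
    msg <- c(msg, "fps must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Construct a PoseSequence3D
#'
#' @param positions Array `[frames, landmarks, 3]` in meters.
#' @param valid Logical `[frames, landmarks]` matrix; defaults to finiteness of
#'   the positions.
#' @param landmarkNames Landmark names.
#' @param fps Frame rate (Hz).
#' @return A [PoseSequence3D-class].
#' @export
poseSequence <- function(positions, valid = NULL, landmarkNames = NULL, fps = 30) {
  if (is.null(landmarkNames)) {
    landmarkNames <- dimnames(positions)[[2]]
    if (is.null(landmarkNames))
      landmarkNames <- paste0("lm", seq_len(dim(positions)[2]))
  }
  if (is.null(valid)) valid <- apply(is.finite(positions), c(1, 2), all)
  positions[rep(!valid, 3L)] <- NA_real_
  dimnames(positions) <- list(NULL, landmarkNames, c("x", "y", "z"))
  dimnames(valid) <- list(NULL, landmarkNames)
  new("PoseSequence3D", positions = positions, valid = valid,
      landmarkNames = landmarkNames, fps = as.numeric(fps))
}

#' @describeIn poseSequence Number of frames.
#' @param x A [PoseSequence3D-class].
#' @export
nFrames <- function(x) dim(x@positions)[1]

#' @describeIn poseSequence Positions array accessor.
#' @export
posePositions <- function(x) x@positions

#' @describeIn poseSequence Validity matrix accessor.
#' @export
poseValid <- function(x) x@valid

#' @describeIn poseSequence One frame's pose as a `[landmarks, 3]` matrix.
#' @param frame Frame index (1-based).
#' @export
poseFrame <- function(x, frame) {
  m <- x@positions[frame, , , drop = FALSE]
  dim(m) <- dim(x@positions)[2:3]
  dimnames(m) <- list(x@landmarkNames, c("x", "y", "z"))
  m
}

#' @export
setMethod("show", "PoseSequence3D", function(object) {
  cat(sprintf("PoseSequence3D: %d frames x %d landmarks at %g fps (%.1f%% valid)\n",
              nFrames(object), length(object@landmarkNames), object@fps,
              100 * mean(object@valid)))
})

# ---------------------------------------------------------------------------
# ActionLabels
# ---------------------------------------------------------------------------

#' Per-frame action labels
#'
#' @slot labels Factor with levels [ACTION_LEVELS].
#' @slot fps Frame rate (Hz).
#' @seealso [actionLabels()]
#' @export
setClass("ActionLabels", representation(labels = "factor", fps = "numeric"))

setValidity("ActionLabels", function(object) {
  if (!all(levels(object@labels) %in% ACTION_LEVELS))
    return("labels must use the fixed action vocabulary")
  if (length(object@fps) != 1L || object@fps <= 0)
    return("fps must be a positive scalar")
  TRUE
})

#' Construct ActionLabels
#'
#' @param labels Character or factor vector of per-frame actions.
#' @param fps Frame rate (Hz).
#' @return An [ActionLabels-class].
#' @export
actionLabels <- function(labels, fps = 30) {
  new("ActionLabels", labels = factor(as.character(labels), levels = ACTION_LEVELS),
      fps = as.numeric(fps))
}

#' @describeIn actionLabels Labels accessor (factor).
#' @param x An [ActionLabels-class].
#' @export
labelVector <- function(x) x@labels

#' @export
setMethod("show", "ActionLabels", function(object) {
  tb <- table(object@labels)
  cat(sprintf("ActionLabels: %d frames at %g fps\n", length(object@labels), object@fps))
  cat("  ", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
})

#' @export
setMethod("length", "ActionLabels", function(x) length(x@labels))

# ---------------------------------------------------------------------------
# AnnotationSet
# ---------------------------------------------------------------------------

#' Human and propagated 2D annotations
#'
#' Like a [DetectionSet-class] but with `source` restricted to `"human"` /
#' `"propagated"` and a logical `flagged` column carrying the result of
#' geometric verification (meaningful for human annotations only).
#'
#' @slot records Data.frame with columns `frame`, `camera_id`, `landmark`,
#'   `x`, `y`, `source`, `flagged`.
#' @slot landmarkNames Landmark vocabulary.
#' @seealso [annotationSet()], [verifyAnnotations()], [propagateLabels()]
#' @export
setClass("AnnotationSet", representation(
  records = "data.frame",
  landmarkNames = "character"
))

setValidity("AnnotationSet", function(object) {
  msg <- character()
  need <- c("frame", "camera_id", "landmark", "x", "y", "source", "flagged")
  if (!all(need %in% names(object@records)))
    msg <- c(msg, paste("records must contain columns:", paste(need, collapse = ", ")))
  else {
    r <- object@records
    if (nrow(r)) {
      if (!all(r$source %in% c("human", "propagated")))
        msg <- c(msg, "source must be 'human' or 'propagated'")
      if (anyDuplicated(r[c("frame", "camera_id", "landmark")]))
        msg <- c(msg, "(frame, camera_id, landmark) must be unique")
      if (any(r$flagged & r$source != "human"))
        msg <- c(msg, "flagged is only meaningful for human annotations")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AnnotationSet
#'
#' @param records Data.frame with at least `frame`, `camera_id`, `landmark`,
#'   `x`, `y`; `source` defaults to `"human"` and `flagged` to `FALSE`.
#' @param landmarkNames Landmark vocabulary.
#' @return An [AnnotationSet-class].
#' @export
annotationSet <- function(records, landmarkNames = unique(records$landmark)) {
  if (is.null(records$source)) records$source <- "human"
  if (is.null(records$flagged)) records$flagged <- FALSE
  records$frame <- as.integer(records$frame)
  records$camera_id <- as.character(records$camera_id)
  records$landmark <- as.character(records$landmark)
  rownames(records) <- NULL
  new("AnnotationSet", records = records, landmarkNames = landmarkNames)
}

#' @describeIn annotationSet Records accessor.
#' @param x An [AnnotationSet-class].
#' @export
annotationRecords <- function(x) x@records

#' @export
setMethod("show", "AnnotationSet", function(object) {
  r <- object@records
  cat(sprintf("AnnotationSet: %d records (%d human, %d propagated, %d flagged)\n",
              nrow(r), sum(r$source == "human"), sum(r$source == "propagated"),
              sum(r$flagged)))
})
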