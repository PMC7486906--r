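# Annotation-efficiency machinery: keyframe selection, crop windows,
# informative-view proposal, geometric verification, cross-view label
# propagation, and the affine augmentation family.

#' Robust 3D center of mass from per-view centroids
#'
#' Triangulates the per-camera 2D body centroids of one frame with RANSAC.
#' Because a perspective projection of a 3D centroid is not exactly the
#' centroid of the projections, the inlier gate is looser than for landmark
#' triangulation.
#'
#' @param centroids Data.frame with columns `camera_id`, `x`, `y` (one frame).
#' @param cameras List of [CameraModel-class].
#' @param inlierThresholdPx RANSAC inlier gate (pixels).
#' @return List as from [triangulateRANSAC()] (`valid = FALSE` with < 2 views).
#' @export
centerOfMass3D <- function(centroids, cameras, inlierThresholdPx = 30) {
  ids <- vapply(cameras, cameraId, character(1))
  m <- match(centroids$camera_id, ids)
  keep <- !is.na(m)
  if (sum(keep) < 2L)
    return(list(point = rep(NA_real_, 3), valid = FALSE,
                inlierCameraIds = character(), meanReprojectionError = NA_real_))
  triangulateRANSAC(cameras[m[keep]],
                    cbind(centroids$x[keep], centroids$y[keep]),
                    inlierThresholdPx = inlierThresholdPx)
}

#' Center-of-mass trajectory over frames
#'
#' @param centroids Data.frame with columns `frame`, `camera_id`, `x`, `y`.
#' @inheritParams centerOfMass3D
#' @return `[frames, 3]` matrix (rows `NA` where triangulation failed).
#' @export
comTrajectory <- function(centroids, cameras, inlierThresholdPx = 30) {
  frames <- sort(unique(centroids$frame))
  out <- matrix(NA_real_, max(frames), 3L)
  for (f in frames) {
    res <- centerOfMass3D(centroids[centroids$frame == f, , drop = FALSE],
                          cameras, inlierThresholdPx)
    if (res$valid) out[f, ] <- res$point
  }
  out
}

#' Select keyframes by translational movement
#'
#' A keyframe is a frame whose center of mass has moved more than
#' `displacementThreshold` meters since the last retained keyframe; the first
#' frame is always retained. Measuring displacement to the last keyframe
#' (rather than the immediately preceding frame) lets slow drift accumulate,
#' so sustained locomotion is sampled at regular spatial intervals.
#'
#' @param com `[frames, 3]` center-of-mass trajectory (rows may be `NA`).
#' @param displacementThreshold Meters (default 0.15).
#' @return Integer vector of selected frame indices (1-based).
#' @export
selectKeyframes <- function(com, displacementThreshold = 0.15) {
  if (is.null(dim(com))) com <- matrix(com, ncol = 3L)
  if (nrow(com) < 1L) stop("trajectory must be nonempty")
  keys <- integer(0)
  last <- NULL
  for (f in seq_len(nrow(com))) {
    if (any(is.na(com[f, ]))) next
    if (is.null(last)) {
      keys <- f; last <- com[f, ]; next
    }
    if (vnorm(com[f, ] - last) > displacementThreshold) {
      keys <- c(keys, f); last <- com[f, ]
    }
  }
  keys
}

#' Distance-adaptive crop window
#'
#' Square crop centered at the projection of the 3D center of mass, with side
#' inversely proportional to the camera-to-subject distance so the subject
#' appears at a roughly constant pixel size after resizing to
#' `outputSize x outputSize`. With the default `scaleConst`, a 1 m subject
#' fills roughly 55% of the crop.
#'
#' @param com3 Length-3 world point (meters).
#' @param camera A [CameraModel-class].
#' @param referenceSize Nominal subject size (meters).
#' @param scaleConst Side = `scaleConst * referenceSize / distance` (pixels).
#' @param outputSize Resized crop resolution (pixels).
#' @param clip Clamp the window inside the image bounds.
#' @return A `CropWindow` (classed list with `cameraId`, `center`, `side`,
#'   `outputSize`).
#' @export
cropWindow <- function(com3, camera, referenceSize = 1.0, scaleConst = 1400,
                       outputSize = 368L, clip = TRUE) {
  if (pointDepth(camera, com3) <= 0)
    stop("behind-camera: center of mass has non-positive depth")
  d <- vnorm(com3 - cameraCenter(camera))
  side <- scaleConst * referenceSize / d
  ctr <- as.numeric(projectPoints(camera, com3))
  if (clip) {
    W <- camera@imageSize[1]; H <- camera@imageSize[2]
    side <- min(side, W, H)
    ctr[1] <- min(max(ctr[1], side / 2 - 0.5), W - 1 - side / 2 + 0.5)
    ctr[2] <- min(max(ctr[2], side / 2 - 0.5), H - 1 - side / 2 + 0.5)
  }
  structure(list(cameraId = cameraId(camera), center = ctr, side = side,
                 outputSize = as.integer(outputSize)),
            class = "CropWindow")
}

#' Map between crop and full-image pixel coordinates
#'
#' @param crop A `CropWindow`.
#' @param px `[n, 2]` pixel matrix (or length-2 vector).
#' @return `[n, 2]` matrix in the other coordinate system.
#' @export
cropToImage <- function(crop, px) {
  if (is.null(dim(px))) px <- matrix(px, ncol = 2L)
  s <- crop$side / crop$outputSize
  orig <- crop$center - crop$side / 2
  cbind(x = (px[, 1] + 0.5) * s - 0.5 + orig[1],
        y = (px[, 2] + 0.5) * s - 0.5 + orig[2])
}

#' @describeIn cropToImage Inverse mapping (image to crop coordinates).
#' @export
imageToCrop <- function(crop, px) {
  if (is.null(dim(px))) px <- matrix(px, ncol = 2L)
  s <- crop$outputSize / crop$side
  orig <- crop$center - crop$side / 2
  cbind(x = (px[, 1] - orig[1] + 0.5) * s - 0.5,
        y = (px[, 2] - orig[2] + 0.5) * s - 0.5)
}

#' Propose informative views for annotation
#'
#' Greedy max-min selection of `k` cameras for manual annotation: start from
#' the camera that sees the center of mass most centrally, then repeatedly
#' add the visible camera maximizing its minimum optical-center distance to
#' the already-selected set (maximal baselines, minimal redundancy).
#'
#' @param com3 Length-3 world point.
#' @param cameras List of [CameraModel-class].
#' @param visible Optional logical vector; defaults to "center of mass
#'   projects inside the image with positive depth".
#' @param k Number of views to select (3-4 in practice).
#' @return Character vector of camera ids.
#' @export
proposeAnnotationViews <- function(com3, cameras, visible = NULL, k = 3L) {
  ids <- vapply(cameras, cameraId, character(1))
  W <- cameras[[1]]@imageSize[1]; H <- cameras[[1]]@imageSize[2]
  score <- rep(Inf, length(cameras))
  if (is.null(visible)) {
    visible <- logical(length(cameras))
    for (i in seq_along(cameras)) {
      if (pointDepth(cameras[[i]], com3) <= 0) next
      p <- projectPoints(cameras[[i]], com3)
      visible[i] <- p[1] >= 0 && p[1] <= W - 1 && p[2] >= 0 && p[2] <= H - 1
      if (visible[i])
        score[i] <- vnorm(p - c((W - 1) / 2, (H - 1) / 2))
    }
  } else {
    for (i in which(visible))
      score[i] <- vnorm(projectPoints(cameras[[i]], com3) - c((W - 1) / 2, (H - 1) / 2))
  }
  cand <- which(visible)
  if (!length(cand)) stop("no camera sees the center of mass")
  if (length(cand) <= k) {
    if (length(cand) < k)
      warning("fewer than k visible cameras; returning all ", length(cand))
    return(ids[cand])
  }
  centers <- t(vapply(cameras, cameraCenter, numeric(3)))
  sel <- cand[which.min(score[cand])]
  while (length(sel) < k) {
    rest <- setdiff(cand, sel)
    dmin <- vapply(rest, function(i)
      min(sqrt(rowSums((centers[sel, , drop = FALSE] -
                          matrix(centers[i, ], length(sel), 3L, byrow = TRUE))^2))),
      numeric(1))
    sel <- c(sel, rest[which.max(dmin)])
  }
  ids[sel]
}

#' Geometric verification of annotations
#'
#' For each (frame, landmark) annotated by humans in at least two views, the
#' landmark is robustly triangulated and reprojected into every annotated
#' view; annotations with reprojection error above `reprojThresholdPx`
#' (default 10 px) are flagged as outliers. Landmarks with fewer than two
#' views are reported as unverifiable, not flagged.
#'
#' @param ann An [AnnotationSet-class] (human records are verified).
#' @param cameras List of [CameraModel-class].
#' @param reprojThresholdPx Flagging gate (pixels), default 10.
#' @return List with `annotations` (the input with `flagged` updated) and
#'   `report` (data.frame `frame`, `camera_id`, `landmark`, `error_px`,
#'   `flagged`, `verifiable`).
#' @export
verifyAnnotations <- function(ann, cameras, reprojThresholdPx = 10) {
  ids <- vapply(cameras, cameraId, character(1))
  rec <- ann@records
  hum <- which(rec$source == "human")
  rep_rows <- list()
  flagged <- rec$flagged
  for (key in split(hum, paste(rec$frame[hum], rec$landmark[hum], sep = "\r"))) {
    sub <- rec[key, ]
    m <- match(sub$camera_id, ids)
    if (length(key) < 2L || anyNA(m)) {
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        frame = sub$frame, camera_id = sub$camera_id, landmark = sub$landmark,
        error_px = NA_real_, flagged = FALSE, verifiable = FALSE)
      next
    }
    tri <- triangulateRANSAC(cameras[m], cbind(sub$x, sub$y),
                             inlierThresholdPx = reprojThresholdPx)
    if (!tri$valid) {
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        frame = sub$frame, camera_id = sub$camera_id, landmark = sub$landmark,
        error_px = NA_real_, flagged = FALSE, verifiable = FALSE)
      next
    }
    errs <- reprojectionErrors(tri$point, cameras[m], cbind(sub$x, sub$y))
    fl <- errs > reprojThresholdPx
    flagged[key] <- fl
    rep_rows[[length(rep_rows) + 1L]] <- data.frame(
      frame = sub$frame, camera_id = sub$camera_id, landmark = sub$landmark,
      error_px = errs, flagged = fl, verifiable = TRUE)
  }
  rec$flagged <- flagged
  list(annotations = annotationSet(rec, ann@landmarkNames),
       report = do.call(rbind, rep_rows))
}

#' Write a verification report as TSV
#'
#' @param report Report data.frame from [verifyAnnotations()].
#' @param path File path.
#' @export
writeFlagReport <- function(report, path) {
  utils::write.table(report, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cross-view label propagation
#'
#' Each landmark verified in at least two unflagged human views is
#' triangulated and projected into every other camera where it is visible
#' (inside the image with positive depth); the projections are added as
#' `source = "propagated"` records. Labels are occlusion-agnostic: a landmark
#' hidden by the body in some view still receives its projected label there,
#' so downstream detector training sees consistent geometry.
#'
#' @param ann A verified [AnnotationSet-class] (see [verifyAnnotations()]).
#' @param cameras List of [CameraModel-class].
#' @return An [AnnotationSet-class] with human plus propagated records.
#' @export
propagateLabels <- function(ann, cameras) {
  ids <- vapply(cameras, cameraId, character(1))
  W <- cameras[[1]]@imageSize[1]; H <- cameras[[1]]@imageSize[2]
  rec <- ann@records
  hum <- which(rec$source == "human")
  out <- list(rec[hum, ])
  for (key in split(hum, paste(rec$frame[hum], rec$landmark[hum], sep = "\r"))) {
    sub <- rec[key, ]
    good <- !sub$flagged
    m <- match(sub$camera_id[good], ids)
    if (sum(good) < 2L || anyNA(m)) {
      warning("landmark '", sub$landmark[1], "' frame ", sub$frame[1],
              " unverifiable; skipped")
      next
    }
    X <- triangulateDLT(cameras[m], cbind(sub$x[good], sub$y[good]))
    others <- setdiff(seq_along(cameras), match(sub$camera_id, ids))
    if (!length(others)) next
    prop <- lapply(others, function(i) {
      if (pointDepth(cameras[[i]], X) <= 0) return(NULL)
      p <- projectPoints(cameras[[i]], X)
      if (p[1] < 0 || p[1] > W - 1 || p[2] < 0 || p[2] > H - 1) return(NULL)
      data.frame(frame = sub$frame[1], camera_id = ids[i],
                 landmark = sub$landmark[1], x = p[1], y = p[2],
                 source = "propagated", flagged = FALSE)
    })
    out <- c(out, prop)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  annotationSet(res, ann@landmarkNames)
}

#' Annotation amplification factor
#'
#' Ratio of total (human + propagated) labels to human labels, the
#' multiview-augmentation gain.
#'
#' @param ann An [AnnotationSet-class] after [propagateLabels()].
#' @return Numeric scalar.
#' @export
amplificationFactor <- function(ann) {
  r <- ann@records
  nrow(r) / sum(r$source == "human")
}

#' The affine augmentation family
#'
#' Applies the fixed family of nine affine transforms to a labeled crop:
#' rotations of +30 and -30 degrees about the crop center, shifts of 20% of
#' the side in each of the four directions, scalings by 1.1 and 0.9 about the
#' center, and a horizontal flip. The flip also swaps bilateral left/right
#' landmark labels. Labels transformed out of the crop are marked invalid.
#'
#' @param labels `[landmarks, 2]` matrix of crop-coordinate labels with
#'   landmark rownames.
#' @param bilateralPairs Two-column character matrix of (left, right) names.
#' @param cropSize Crop side in pixels (default 368).
#' @return Named list of 9 elements, each `list(labels, valid)`.
#' @export
affineAugment <- function(labels, bilateralPairs, cropSize = 368L) {
  S <- cropSize
  ctr <- (S - 1) / 2
  rot <- function(deg) {
    th <- deg * pi / 180
    R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
    t(R %*% (t(labels) - ctr)) + ctr
  }
  shift <- function(dx, dy) sweep(labels, 2L, -c(dx, dy))
  scl <- function(s) (labels - ctr) * s + ctr
  d <- 0.2 * S
  flip <- labels
  flip[, 1] <- (S - 1) - flip[, 1]
  if (nrow(bilateralPairs)) {
    nm <- rownames(flip)
    for (i in seq_len(nrow(bilateralPairs))) {
      a <- match(bilateralPairs[i, 1], nm); b <- match(bilateralPairs[i, 2], nm)
      if (!is.na(a) && !is.na(b)) flip[c(a, b), ] <- flip[c(b, a), ]
    }
  }
  fam <- list(
    rot_p30 = rot(30), rot_m30 = rot(-30),
    shift_left = shift(-d, 0), shift_right = shift(d, 0),
    shift_up = shift(0, -d), shift_down = shift(0, d),
    scale_110 = scl(1.1), scale_090 = scl(0.9),
    hflip = flip)
  lapply(fam, function(L) {
    valid <- L[, 1] >= 0 & L[, 1] <= S - 1 & L[, 2] >= 0 & L[, 2] <= S - 1
    list(labels = L, valid = valid)
  })
}

# --------------------------------------------------------------------------
# COCO-keypoints-style JSON interchange
# --------------------------------------------------------------------------

#' Write detections or annotations as COCO-keypoints-style JSON
#'
#' One image entry per (frame, camera); one annotation entry per image with
#' the landmark keypoints flattened as `(x, y, v)` triplets (`v = 2` labeled,
#' `0` missing). Extension fields `source`, `flagged` and `confidence` carry
#' the package-specific provenance.
#'
#' @param x A [DetectionSet-class] or [AnnotationSet-class].
#' @param path File path.
#' @export
writeKeypointsJSON <- function(x, path) {
  rec <- if (is(x, "DetectionSet")) x@records else x@records
  lm <- x@landmarkNames
  if (is.null(rec$confidence)) rec$confidence <- 1
  if (is.null(rec$flagged)) rec$flagged <- FALSE
  keys <- unique(rec[c("frame", "camera_id")])
  keys <- keys[order(keys$frame, keys$camera_id), , drop = FALSE]
  images <- vector("list", nrow(keys)); annotations <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- rec[rec$frame == keys$frame[i] & rec$camera_id == keys$camera_id[i], ]
    kp <- numeric(3 * length(lm)); src <- character(length(lm))
    conf <- numeric(length(lm)); flg <- logical(length(lm))
    j <- match(sub$landmark, lm)
    kp[3 * j - 2] <- sub$x; kp[3 * j - 1] <- sub$y; kp[3 * j] <- 2
    src[j] <- sub$source; conf[j] <- sub$confidence; flg[j] <- sub$flagged
    images[[i]] <- list(id = i, frame = keys$frame[i],
                        camera_id = keys$camera_id[i])
    annotations[[i]] <- list(image_id = i, category_id = 1L,
                             keypoints = kp, num_keypoints = length(j),
                             source = src, confidence = conf, flagged = flg)
  }
  js <- list(images = images, annotations = annotations,
             categories = list(list(id = 1L, name = "subject", keypoints = lm)))
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read COCO-keypoints-style JSON
#'
#' @param path File path.
#' @param as `"detections"` or `"annotations"`.
#' @return A [DetectionSet-class] or [AnnotationSet-class].
#' @export
readKeypointsJSON <- function(path, as = c("detections", "annotations")) {
  as <- match.arg(as)
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lm <- unlist(js$categories[[1]]$keypoints)
  imgs <- js$images
  imap <- list()
  for (im in imgs) imap[[as.character(im$id)]] <- im
  rows <- list()
  for (a in js$annotations) {
    im <- imap[[as.character(a$image_id)]]
    kp <- unlist(a$keypoints)
    v <- kp[seq(3, length(kp), by = 3)]
    pres <- which(v > 0)
    if (!length(pres)) next
    rows[[length(rows) + 1L]] <- data.frame(
      frame = im$frame, camera_id = im$camera_id, landmark = lm[pres],
      x = kp[3 * pres - 2], y = kp[3 * pres - 1],
      confidence = unlist(a$confidence)[pres],
      source = unlist(a$source)[pres],
      flagged = as.logical(unlist(a$flagged))[pres],
      stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, rows)
  if (as == "detections") {
    rec$flagged <- NULL
    detectionSet(rec, landmarkNames = lm)
  } else {
    rec$confidence <- NULL
    annotationSet(rec, landmarkNames = lm)
  }
}
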