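# Synthetic studio: everything the real system records -- rig, articulated
# skeleton trajectories, centroids, noisy detections, and training-style
# response maps -- generated in code so the full pipeline is testable without
# image data or a trained detector.

#' Rig specification
#'
#' Describes the multi-camera capture rig: an open enclosure encircled by
#' cameras evenly spaced on horizontal rings just outside the walls, all
#' facing the enclosure center. The default reproduces a 62-camera, two-level
#' rig around a 2.45 x 2.45 x 2.75 m enclosure with ~0.35 m adjacent-camera
#' baselines; camera positions near the enclosure corners end up at ~45
#' degree azimuth because every camera looks at the center.
#'
#' @param enclosure Enclosure extents (x, y, z) in meters.
#' @param nCameras Total number of cameras (>= 2).
#' @param nLevels Number of horizontal camera rings.
#' @param cornerAngleDeg Nominal corner-camera azimuth (informational; the
#'   look-at-center construction realizes it).
#' @param targetBaseline Desired adjacent same-level camera spacing (meters);
#'   sets the ring radius unless that would fall inside the enclosure.
#' @param focal Focal length in pixels (applies to fx and fy).
#' @param imageSize Image (width, height) in pixels.
#' @return A `RigSpec` (classed list).
#' @export
rigSpec <- function(enclosure = c(2.45, 2.45, 2.75), nCameras = 62L,
                    nLevels = 2L, cornerAngleDeg = 45,
                    targetBaseline = 0.35, focal = 780,
                    imageSize = c(1280L, 1024L)) {
  if (nCameras < 2L) stop("a rig needs at least 2 cameras")
  if (any(enclosure <= 0)) stop("enclosure extents must be positive")
  structure(list(enclosure = enclosure, nCameras = as.integer(nCameras),
                 nLevels = as.integer(nLevels), cornerAngleDeg = cornerAngleDeg,
                 targetBaseline = targetBaseline, focal = focal,
                 imageSize = as.integer(imageSize)),
            class = "RigSpec")
}

#' Build the camera rig
#'
#' Cameras are distributed as evenly as possible across `nLevels` horizontal
#' rings encircling the enclosure; within a ring they are evenly spaced in
#' azimuth (rings are staggered by half a spacing), and every camera's
#' optical axis passes through the enclosure center. The ring radius is
#' chosen so adjacent same-level cameras sit `targetBaseline` apart, but
#' never inside the enclosure footprint.
#'
#' @param spec A [rigSpec()].
#' @return List of [CameraModel-class] objects (ids `cam01`, `cam02`, ...).
#' @examples
#' rig <- makeRig(rigSpec(nCameras = 8, nLevels = 1))
#' length(rig)
#' @export
makeRig <- function(spec = rigSpec()) {
  stopifnot(inherits(spec, "RigSpec"))
  n <- spec$nCameras
  L <- max(1L, spec$nLevels)
  perLevel <- rep(n %/% L, L)
  extra <- n %% L
  if (extra > 0L) perLevel[seq_len(extra)] <- perLevel[seq_len(extra)] + 1L
  half <- spec$enclosure[1:2] / 2
  halfDiag <- sqrt(sum(half^2))
  m <- max(perLevel)
  radius <- if (m >= 2L) (spec$targetBaseline / 2) / sin(pi / m) else halfDiag + 0.3
  if (radius < 0.99 * halfDiag) radius <- halfDiag + 0.3
  H <- spec$enclosure[3]
  zFrac <- if (L == 1L) 0.55 else seq(0.35, 0.75, length.out = L)
  center <- c(0, 0, H / 2)
  cams <- vector("list", n)
  k <- 0L
  fmt <- paste0("cam%0", max(2L, nchar(n)), "d")
  for (lvl in seq_len(L)) {
    mL <- perLevel[lvl]
    spacing <- 2 * pi / mL
    offset <- (lvl - 1L) * spacing / 2
    for (j in seq_len(mL)) {
      k <- k + 1L
      az <- offset + (j - 1L) * spacing
      eye <- c(radius * cos(az), radius * sin(az), zFrac[lvl] * H)
      R <- lookAtRotation(eye, center)
      cams[[k]] <- cameraModel(sprintf(fmt, k),
                               focal = spec$focal,
                               principalPoint = (spec$imageSize - 1) / 2,
                               rotation = R, translation = as.numeric(-R %*% eye),
                               imageSize = spec$imageSize)
    }
  }
  cams
}

#' Default 13-landmark skeleton
#'
#' The default landmark list (nose, head, neck, shoulders, hands, hip, knees,
#' feet, tail) with a kinematic tree rooted at the neck, rest limb lengths
#' sized to an adult macaque, and the four bilateral left/right pairs. The
#' landmark set is configurable through [skeleton()]; this default is the one
#' the synthetic studio animates.
#'
#' @return A [Skeleton-class].
#' @export
defaultSkeleton <- function() {
  lm <- c("nose", "head", "neck", "left_shoulder", "right_shoulder",
          "left_hand", "right_hand", "hip", "left_knee", "right_knee",
          "left_foot", "right_foot", "tail")
  parents <- c(nose = "head", head = "neck", neck = NA,
               left_shoulder = "neck", right_shoulder = "neck",
               left_hand = "left_shoulder", right_hand = "right_shoulder",
               hip = "neck", left_knee = "hip", right_knee = "hip",
               left_foot = "left_knee", right_foot = "right_knee",
               tail = "hip")[lm]
  lens <- c(nose = 0.09, head = 0.11, left_shoulder = 0.10,
            right_shoulder = 0.10, left_hand = 0.28, right_hand = 0.28,
            hip = 0.35, left_knee = 0.17, right_knee = 0.17,
            left_foot = 0.20, right_foot = 0.20, tail = 0.25)
  pairs <- rbind(c("left_shoulder", "right_shoulder"),
                 c("left_hand", "right_hand"),
                 c("left_knee", "right_knee"),
                 c("left_foot", "right_foot"))
  skeleton(lm, parents, lens, pairs)
}

#' Motion script
#'
#' An ordered list of scripted action segments. Each segment is a list with
#' `action` (one of [ACTION_LEVELS]), `duration` in seconds, and optional
#' `params` (e.g. `speed`, `turnRate` deg/s, `straight = TRUE` to suppress
#' heading wander).
#'
#' @param segments List of segments, e.g.
#'   `list(list(action = "sit", duration = 5))`.
#' @param fps Frame rate (Hz), default 30.
#' @return A `MotionScript` (classed list).
#' @export
motionScript <- function(segments, fps = 30) {
  for (s in segments) {
    if (!s$action %in% ACTION_LEVELS)
      stop("unknown action label: ", s$action)
    if (is.null(s$duration) || s$duration <= 0)
      stop("segment durations must be positive")
  }
  structure(list(segments = segments, fps = fps), class = "MotionScript")
}

#' Detection noise model
#'
#' Parameters of the detector emulator: per-axis Gaussian pixel noise, gross
#' outlier probability, miss probability, and geometric torso-capsule
#' occlusion.
#'
#' @param pixelSigma Gaussian noise standard deviation (pixels).
#' @param outlierProb Probability of a gross outlier (uniform in-image pixel).
#' @param missProb Probability of a missed detection.
#' @param occlusion Logical; convert torso-occluded landmarks to misses.
#' @param occlusionRadius Torso capsule radius (meters).
#' @param seed RNG seed.
#' @return A `NoiseModel` (classed list).
#' @export
noiseModel <- function(pixelSigma = 2, outlierProb = 0.1, missProb = 0.02,
                       occlusion = TRUE, occlusionRadius = 0.12, seed = 1L) {
  stopifnot(pixelSigma >= 0, outlierProb >= 0, outlierProb <= 1,
            missProb >= 0, missProb <= 1)
  structure(list(pixelSigma = pixelSigma, outlierProb = outlierProb,
                 missProb = missProb, occlusion = occlusion,
                 occlusionRadius = occlusionRadius, seed = seed),
            class = "NoiseModel")
}

# --------------------------------------------------------------------------
# Scripted articulated motion
# --------------------------------------------------------------------------

# Compose a 13-landmark pose from the neck position and unit direction
# vectors for every (parent -> child) edge; limb lengths are taken from the
# skeleton's rest lengths exactly (directions are normalized here).
composePose <- function(skel, neck, dirs) {
  lm <- skel@landmarkNames
  pos <- matrix(NA_real_, length(lm), 3L, dimnames = list(lm, c("x", "y", "z")))
  pos[skeletonRoot(skel), ] <- neck
  for (child in breadthFirstOrder(skel)[-1L]) {
    par <- skel@parents[[child]]
    pos[child, ] <- pos[par, ] + unitv(dirs[[child]]) * skel@restLengths[[child]]
  }
  pos
}

# Per-action posture: given facing f (horizontal unit), left = up x f, and a
# gait phase, return neck height, spine direction and per-edge directions.
# `jit` is a named list of small jitter vectors added before normalization,
# which perturbs directions while keeping limb lengths exact.
postureDirs <- function(action, f, phase = 0, jit = NULL) {
  up <- c(0, 0, 1)
  left <- pracmaFreeCross(up, f)
  J <- function(nm) if (is.null(jit)) c(0, 0, 0) else jit[[nm]]
  sw <- sin(phase); swo <- sin(phase + pi)  # contralateral gait swing
  d <- switch(action,
    sit = list(
      neckZ = 0.50,
      hip = -0.94 * up - 0.34 * f,
      head = 0.9 * up + 0.44 * f, nose = 0.9 * f - 0.44 * up,
      left_shoulder = left, right_shoulder = -left,
      left_hand = 0.5 * f - 0.85 * up + 0.1 * left,
      right_hand = 0.5 * f - 0.85 * up - 0.1 * left,
      left_knee = 0.8 * f + 0.35 * left - 0.3 * up,
      right_knee = 0.8 * f - 0.35 * left - 0.3 * up,
      left_foot = 0.95 * f + 0.1 * left + 0.1 * up,
      right_foot = 0.95 * f - 0.1 * left + 0.1 * up,
      tail = -0.7 * f - 0.3 * up),
    stand = list(  # upright bipedal stance, arms tucked by the torso
      neckZ = 0.85,
      hip = -0.97 * up - 0.24 * f,
      head = 0.95 * up + 0.31 * f, nose = f,
      left_shoulder = left, right_shoulder = -left,
      left_hand = 0.07 * f + 0.18 * left - 0.98 * up,
      right_hand = 0.07 * f - 0.18 * left - 0.98 * up,
      left_knee = 0.1 * f + 0.2 * left - 0.97 * up,
      right_knee = 0.1 * f - 0.2 * left - 0.97 * up,
      left_foot = 0.15 * f + 0.05 * left - 0.98 * up,
      right_foot = 0.15 * f - 0.05 * left - 0.98 * up,
      tail = -0.6 * f - 0.8 * up),
    walk = list(  # quadrupedal gait
      neckZ = 0.50 + 0.02 * sin(2 * phase),
      hip = -f,
      head = 0.8 * up + 0.6 * f, nose = f - 0.2 * up,
      left_shoulder = left, right_shoulder = -left,
      left_hand = (0.35 * sw) * f + 0.1 * left - 0.95 * up,
      right_hand = (0.35 * swo) * f - 0.1 * left - 0.95 * up,
      left_knee = (0.3 * swo) * f + 0.25 * left - 0.9 * up,
      right_knee = (0.3 * sw) * f - 0.25 * left - 0.9 * up,
      left_foot = (0.3 * sw) * f + 0.1 * left - 0.95 * up,
      right_foot = (0.3 * swo) * f - 0.1 * left - 0.95 * up,
      tail = -0.5 * f + 0.85 * up),
    climb = list(  # vertical wall posture, arms overhead
      neckZ = NA,  # driven by the segment trajectory
      hip = -0.98 * up + 0.2 * f,
      head = 0.9 * up + 0.44 * f, nose = 0.6 * f + 0.8 * up,
      left_shoulder = left, right_shoulder = -left,
      left_hand = (0.75 + 0.2 * sw) * up + 0.45 * left + 0.4 * f,
      right_hand = (0.75 + 0.2 * swo) * up - 0.45 * left + 0.4 * f,
      left_knee = 0.5 * f + 0.5 * left - 0.6 * up,
      right_knee = 0.5 * f - 0.5 * left - 0.6 * up,
      left_foot = 0.4 * f + 0.2 * left - 0.9 * up,
      right_foot = 0.4 * f - 0.2 * left - 0.9 * up,
      tail = -0.4 * f - 0.9 * up),
    climb_supine = list(  # inverted, hanging under the ceiling
      neckZ = 2.30,
      hip = -f,
      head = 0.5 * f - 0.85 * up, nose = 0.8 * f - 0.6 * up,
      left_shoulder = left, right_shoulder = -left,
      left_hand = (0.3 * sw) * f + 0.25 * left + 0.93 * up,
      right_hand = (0.3 * swo) * f - 0.25 * left + 0.93 * up,
      left_knee = (0.3 * swo) * f + 0.3 * left + 0.9 * up,
      right_knee = (0.3 * sw) * f - 0.3 * left + 0.9 * up,
      left_foot = (0.3 * sw) * f + 0.1 * left + 0.95 * up,
      right_foot = (0.3 * swo) * f - 0.1 * left + 0.95 * up,
      tail = -0.6 * f - 0.8 * up),
    jump = list(  # tucked ballistic posture
      neckZ = NA,
      hip = -0.85 * f - 0.5 * up,
      head = 0.7 * up + 0.7 * f, nose = f + 0.2 * up,
      left_shoulder = left, right_shoulder = -left,
      left_hand = 0.8 * f + 0.15 * left - 0.55 * up,
      right_hand = 0.8 * f - 0.15 * left - 0.55 * up,
      left_knee = 0.6 * f + 0.3 * left - 0.7 * up,
      right_knee = 0.6 * f - 0.3 * left - 0.7 * up,
      left_foot = -0.4 * f + 0.1 * left - 0.5 * up,
      right_foot = -0.4 * f - 0.1 * left - 0.5 * up,
      tail = -0.8 * f + 0.4 * up),
    stop("unknown action label: ", action))
  edges <- setdiff(names(d), "neckZ")
  dirs <- lapply(edges, function(nm) d[[nm]] + J(nm))
  names(dirs) <- edges
  list(neckZ = d$neckZ, dirs = dirs)
}

#' Simulate scripted articulated motion
#'
#' Generates a per-frame 13-landmark ground-truth pose sequence from a motion
#' script built of parameterized primitives: quasi-static sitting and
#' standing with small jitter, a periodic quadrupedal gait translating along
#' the floor, vertical climbing and inverted ceiling traversal, and ballistic
#' jumps (g = 9.81 m/s^2). Limb lengths equal the skeleton's rest lengths
#' exactly in every frame; all landmarks stay inside the enclosure. The
#' generator is bit-reproducible given `seed`.
#'
#' @param skel A [Skeleton-class]; the default skeleton is animated.
#' @param script A [motionScript()].
#' @param seed RNG seed for jitter and heading wander.
#' @param enclosure Enclosure extents (meters).
#' @param start Optional list with `position` (x, y) and `headingDeg`.
#' @return List with `poses` (a [PoseSequence3D-class]) and `labels`
#'   (an [ActionLabels-class]).
#' @examples
#' mo <- simulateMotion(script = motionScript(list(
#'   list(action = "sit", duration = 1))), seed = 1)
#' nFrames(mo$poses)
#' @export
simulateMotion <- function(skel = defaultSkeleton(), script, seed = 1L,
                           enclosure = c(2.45, 2.45, 2.75), start = NULL) {
  stopifnot(inherits(script, "MotionScript"))
  if (!length(script$segments)) stop("script must be nonempty")
  fps <- script$fps
  dt <- 1 / fps
  lm <- skel@landmarkNames
  edges <- setdiff(breadthFirstOrder(skel), skeletonRoot(skel))
  # horizontal clamp keeping every landmark inside the walls
  bound <- min(enclosure[1:2]) / 2 - 0.62
  nTot <- sum(vapply(script$segments, function(s) round(s$duration * fps), numeric(1)))
  pos <- array(NA_real_, c(nTot, length(lm), 3L))
  labs <- character(nTot)

  withSeed(seed, {
    xy <- if (is.null(start)) c(0, 0) else start$position
    psi <- if (is.null(start)) 0 else start$headingDeg * pi / 180
    frame <- 0L
    for (seg in script$segments) {
      nF <- round(seg$duration * fps)
      p <- seg$params %||% list()
      action <- seg$action
      speed <- p$speed %||% switch(action, walk = 0.45, climb = 0.35,
                                   climb_supine = 0.25, jump = 1.2, 0)
      gaitHz <- p$gaitHz %||% 1.4
      straight <- isTRUE(p$straight)
      jitterSd <- p$jitter %||% 0.03
      # ballistic setup for jumps: land at take-off height after the segment
      if (action == "jump") {
        T <- nF * dt
        v0 <- 9.81 * T / 2
        avail <- max(0.05, bound - max(abs(xy)) - 0.05)
        speed <- min(speed, avail / T)
        z0 <- NA  # filled below from previous posture (caps v0 by headroom)
      }
      climbDir <- 1
      for (j in seq_len(nF)) {
        frame <- frame + 1L
        t <- (j - 1L) * dt
        phase <- 2 * pi * gaitHz * t
        # heading update
        if (action %in% c("walk", "climb_supine") && j > 1L) {
          turn <- if (straight) 0 else stats::rnorm(1, 0, 25 * pi / 180) * dt
          # steer back toward the interior near the boundary
          ahead <- xy + c(cos(psi), sin(psi)) * speed * 0.6
          if (max(abs(ahead)) > bound) {
            toCenter <- atan2(-xy[2], -xy[1])
            dpsi <- atan2(sin(toCenter - psi), cos(toCenter - psi))
            turn <- turn + sign(dpsi) * 90 * pi / 180 * dt
          }
          psi <- psi + turn
          xy <- xy + c(cos(psi), sin(psi)) * speed * dt
          xy <- pmax(pmin(xy, bound), -bound)
        }
        f <- c(cos(psi), sin(psi), 0)
        jit <- NULL
        if (jitterSd > 0 && action != "jump") {
          jit <- lapply(edges, function(e) stats::rnorm(3, 0, jitterSd))
          names(jit) <- edges
        }
        pd <- postureDirs(action, f, phase, jit)
        neckZ <- pd$neckZ
        if (action == "climb") {
          if (j == 1L) climbZ <- 0.8
          climbZ <- climbZ + climbDir * speed * dt
          if (climbZ > 2.2) { climbZ <- 2.2; climbDir <- -1 }
          if (climbZ < 0.8) { climbZ <- 0.8; climbDir <- 1 }
          neckZ <- climbZ
        } else if (action == "jump") {
          if (j == 1L && is.na(z0)) {
            prevZ <- if (frame > 1L) pos[frame - 1L, match("neck", lm), 3] else 0.5
            z0 <- prevZ
            headroom <- max(0.05, enclosure[3] - 0.40 - z0)
            v0 <- min(v0, sqrt(2 * 9.81 * headroom))
          }
          neckZ <- max(z0 + v0 * t - 0.5 * 9.81 * t^2, 0.45)
          xy <- pmax(pmin(xy + c(cos(psi), sin(psi)) * speed * dt, bound), -bound)
        }
        neck <- c(xy, neckZ)
        if (jitterSd > 0 && action %in% c("sit", "stand"))
          neck <- neck + stats::rnorm(3, 0, 0.004)
        pose <- composePose(skel, neck, pd$dirs)
        # rigid upward shift if anything would dip below the floor
        # (preserves limb lengths exactly)
        low <- min(pose[, 3])
        if (low < 0.02) pose[, 3] <- pose[, 3] + (0.02 - low)
        pos[frame, , ] <- pose
        labs[frame] <- action
      }
    }
  })
  dimnames(pos) <- list(NULL, lm, c("x", "y", "z"))
  list(poses = poseSequence(pos, landmarkNames = lm, fps = fps),
       labels = actionLabels(labs, fps = fps))
}

# --------------------------------------------------------------------------
# Detector emulation
# --------------------------------------------------------------------------

# Vectorized segment-segment minimum distance: rows of (p1, p2) against a
# single segment (q1, q2). Standard clamped closest-point computation.
# Also returns the parameter s (in [0, 1]) along the (p1, p2) segments.
segmentsToSegmentDist <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1
  d2 <- matrix(q2 - q1, nrow(p1), 3L, byrow = TRUE)
  r <- p1 - matrix(q1, nrow(p1), 3L, byrow = TRUE)
  a <- rowSums(d1 * d1); e <- sum((q2 - q1)^2)
  b <- rowSums(d1 * d2); cc <- rowSums(d1 * r); f <- rowSums(d2 * r)
  denom <- a * e - b^2
  s <- ifelse(denom > 1e-12, (b * f - cc * e) / denom, 0)
  s <- pmin(pmax(s, 0), 1)
  t <- if (e > 1e-12) (b * s + f) / e else rep(0, length(s))
  tClamped <- pmin(pmax(t, 0), 1)
  # re-project s where t was clamped
  redo <- t != tClamped
  if (any(redo)) {
    s2 <- (b * tClamped - cc) / pmax(a, 1e-12)
    s[redo] <- pmin(pmax(s2[redo], 0), 1)
  }
  cp <- p1 + d1 * s
  cq <- matrix(q1, nrow(p1), 3L, byrow = TRUE) + d2 * tClamped
  list(dist = sqrt(rowSums((cp - cq)^2)), s = s)
}

# Logical [cameras x landmarks] matrix: TRUE where the sight ray from the
# camera to the landmark passes through the torso capsule (segment neck-hip,
# given radius) clearly before reaching the landmark. The ray is extended
# beyond the landmark so that landmarks sitting on or near the torso surface
# (head, shoulders) do not occlude themselves: only a blocking torso strictly
# between camera and landmark counts.
torsoOcclusionMask <- function(pose, camCenters, neckIdx, hipIdx, radius,
                               margin = 0.05, overshoot = 0.6) {
  nC <- nrow(camCenters); nL <- nrow(pose)
  O <- camCenters[rep(seq_len(nC), each = nL), , drop = FALSE]
  Pt <- pose[rep(seq_len(nL), times = nC), , drop = FALSE]
  dir <- Pt - O
  len <- sqrt(rowSums(dir^2))
  Pend <- O + dir * ((len + overshoot) / len)
  ss <- segmentsToSegmentDist(O, Pend, pose[neckIdx, ], pose[hipIdx, ])
  tStar <- ss$s * (len + overshoot)
  occ <- ss$dist < radius & tStar < len - margin
  matrix(occ, nC, nL, byrow = TRUE)
}

#' Emulate per-view landmark detections
#'
#' Stands in for a trained landmark detector: for each (frame, camera,
#' landmark) it emits, with probability `missProb`, nothing; else with
#' probability `outlierProb` a gross outlier uniform over the image; else the
#' true projection plus per-axis Gaussian noise. Landmarks projecting outside
#' the image or behind the camera are misses, and (optionally) landmarks
#' whose sight ray passes through the torso capsule (neck-hip segment) before
#' reaching the landmark are converted to misses, emulating self-occlusion.
#' Bit-reproducible given the noise model's seed.
#'
#' @param poses Ground-truth [PoseSequence3D-class].
#' @param cameras List of [CameraModel-class].
#' @param noise A [noiseModel()].
#' @return A [DetectionSet-class].
#' @export
emulateDetections <- function(poses, cameras, noise = noiseModel()) {
  lm <- poses@landmarkNames
  nF <- nFrames(poses); nL <- length(lm); nC <- length(cameras)
  P <- matrix(aperm(poses@positions, c(2, 1, 3)), nF * nL, 3L)  # frame-major blocks
  camIds <- vapply(cameras, cameraId, character(1))
  W <- cameras[[1]]@imageSize[1]; H <- cameras[[1]]@imageSize[2]

  proj <- array(NA_real_, c(nF * nL, nC, 2L))
  vis <- matrix(FALSE, nF * nL, nC)
  for (i in seq_len(nC)) {
    depth <- pointDepth(cameras[[i]], P)
    pp <- projectPoints(cameras[[i]], P, clipBehind = TRUE)
    ok <- depth > 0 & is.finite(pp[, 1]) &
      pp[, 1] >= 0 & pp[, 1] <= W - 1 & pp[, 2] >= 0 & pp[, 2] <= H - 1
    proj[, i, ] <- pp
    vis[, i] <- ok
  }

  if (isTRUE(noise$occlusion)) {
    centers <- t(vapply(cameras, cameraCenter, numeric(3)))
    neckIdx <- match("neck", lm); hipIdx <- match("hip", lm)
    if (!is.na(neckIdx) && !is.na(hipIdx)) {
      for (fIdx in seq_len(nF)) {
        rows <- (fIdx - 1L) * nL + seq_len(nL)
        occ <- torsoOcclusionMask(P[rows, , drop = FALSE], centers,
                                  neckIdx, hipIdx, noise$occlusionRadius)
        vis[rows, ] <- vis[rows, ] & t(!occ)
      }
    }
  }

  nCell <- nF * nL * nC
  draws <- withSeed(noise$seed, list(
    miss = stats::runif(nCell), out = stats::runif(nCell),
    nx = stats::rnorm(nCell, 0, noise$pixelSigma),
    ny = stats::rnorm(nCell, 0, noise$pixelSigma),
    ox = stats::runif(nCell, 0, W - 1), oy = stats::runif(nCell, 0, H - 1)))
  miss <- matrix(draws$miss < noise$missProb, nF * nL, nC)
  outl <- matrix(draws$out < noise$outlierProb, nF * nL, nC)

  emit <- vis & !miss
  isOut <- emit & outl
  x <- matrix(draws$ox, nF * nL, nC)
  y <- matrix(draws$oy, nF * nL, nC)
  x[!isOut] <- (proj[, , 1] + matrix(draws$nx, nF * nL, nC))[!isOut]
  y[!isOut] <- (proj[, , 2] + matrix(draws$ny, nF * nL, nC))[!isOut]

  keep <- which(emit)
  rowIdx <- (keep - 1L) %% (nF * nL) + 1L
  camIdx <- (keep - 1L) %/% (nF * nL) + 1L
  rec <- data.frame(
    frame = (rowIdx - 1L) %/% nL + 1L,
    camera_id = camIds[camIdx],
    landmark = lm[(rowIdx - 1L) %% nL + 1L],
    x = x[keep], y = y[keep],
    confidence = 1, source = "detector",
    stringsAsFactors = FALSE)
  rec <- rec[is.finite(rec$x) & is.finite(rec$y), ]
  detectionSet(rec, landmarkNames = lm)
}

#' Emulate per-view body centroids
#'
#' The 2D center of the projected landmark cloud per (frame, camera), standing
#' in for the center of segmented body pixels, with the same miss/outlier/noise
#' semantics as [emulateDetections()] (no occlusion: the whole body is rarely
#' hidden).
#'
#' @inheritParams emulateDetections
#' @return Data.frame with columns `frame`, `camera_id`, `x`, `y`.
#' @export
emulateCentroids <- function(poses, cameras, noise = noiseModel(occlusion = FALSE)) {
  lm <- poses@landmarkNames
  nF <- nFrames(poses); nL <- length(lm); nC <- length(cameras)
  P <- matrix(aperm(poses@positions, c(2, 1, 3)), nF * nL, 3L)
  camIds <- vapply(cameras, cameraId, character(1))
  W <- cameras[[1]]@imageSize[1]; H <- cameras[[1]]@imageSize[2]
  cx <- matrix(NA_real_, nF, nC); cy <- matrix(NA_real_, nF, nC)
  for (i in seq_len(nC)) {
    depth <- pointDepth(cameras[[i]], P)
    pp <- projectPoints(cameras[[i]], P, clipBehind = TRUE)
    ok <- depth > 0 & is.finite(pp[, 1])
    px <- matrix(ifelse(ok, pp[, 1], NA_real_), nF, nL, byrow = TRUE)
    py <- matrix(ifelse(ok, pp[, 2], NA_real_), nF, nL, byrow = TRUE)
    cx[, i] <- rowMeans(px)
    cy[, i] <- rowMeans(py)
  }
  nCell <- nF * nC
  draws <- withSeed(noise$seed, list(
    miss = stats::runif(nCell), out = stats::runif(nCell),
    nx = stats::rnorm(nCell, 0, noise$pixelSigma),
    ny = stats::rnorm(nCell, 0, noise$pixelSigma),
    ox = stats::runif(nCell, 0, W - 1), oy = stats::runif(nCell, 0, H - 1)))
  miss <- matrix(draws$miss < noise$missProb, nF, nC)
  outl <- matrix(draws$out < noise$outlierProb, nF, nC)
  emit <- is.finite(cx) & !miss
  isOut <- emit & outl
  x <- matrix(draws$ox, nF, nC); y <- matrix(draws$oy, nF, nC)
  x[!isOut] <- (cx + matrix(draws$nx, nF, nC))[!isOut]
  y[!isOut] <- (cy + matrix(draws$ny, nF, nC))[!isOut]
  keep <- which(emit)
  data.frame(frame = (keep - 1L) %% nF + 1L,
             camera_id = camIds[(keep - 1L) %/% nF + 1L],
             x = x[keep], y = y[keep], stringsAsFactors = FALSE)
}

# --------------------------------------------------------------------------
# Training-style response maps
# --------------------------------------------------------------------------

#' Render a ground-truth response map
#'
#' A Gaussian bump on the detector output grid centered at the landmark's
#' position in the (square, resized) crop, mapped crop -> grid by dividing by
#' the stride `cropSize / grid` (8 for the 368 -> 46 default). Out-of-crop
#' landmarks yield an all-zero map (the occluded-label convention).
#'
#' @param pixelInCrop Landmark (x, y) in crop coordinates.
#' @param grid Output grid side (default 46).
#' @param sigmaPx Gaussian sigma in crop pixels (default 8).
#' @param cropSize Crop side in pixels (default 368).
#' @return `grid x grid` matrix (rows = y) of nonnegative responses, peak 1.
#' @export
renderResponseMap <- function(pixelInCrop, grid = 46L, sigmaPx = 8,
                              cropSize = 368L) {
  out <- matrix(0, grid, grid)
  p <- as.numeric(pixelInCrop)
  if (any(!is.finite(p)) || any(p < 0) || any(p > cropSize - 1)) return(out)
  stride <- cropSize / grid
  u <- p / stride
  sg <- sigmaPx / stride
  gx <- outer(rep(1, grid), (seq_len(grid) - 1) - u[1])
  gy <- outer((seq_len(grid) - 1) - u[2], rep(1, grid))
  exp(-(gx^2 + gy^2) / (2 * sg^2))
}

#' Stack per-landmark response maps with a background channel
#'
#' @param pose2d `[landmarks, 2]` matrix of crop-coordinate positions (rows
#'   with `NA` yield all-zero channels).
#' @inheritParams renderResponseMap
#' @return `grid x grid x (landmarks + 1)` array; the last channel is the
#'   background `max(0, 1 - max(landmark channels))`.
#' @export
stackResponseMaps <- function(pose2d, grid = 46L, sigmaPx = 8, cropSize = 368L) {
  nL <- nrow(pose2d)
  out <- array(0, c(grid, grid, nL + 1L))
  for (i in seq_len(nL))
    out[, , i] <- renderResponseMap(pose2d[i, ], grid, sigmaPx, cropSize)
  mx <- apply(out[, , seq_len(nL), drop = FALSE], c(1, 2), max)
  out[, , nL + 1L] <- pmax(0, 1 - mx)
  out
}

# --------------------------------------------------------------------------
# Plain-text I/O for generated data
# --------------------------------------------------------------------------

#' Write / read a pose sequence as CSV
#'
#' Long format: `frame, landmark, x, y, z, valid` plus a `stage` tag.
#'
#' @param poses A [PoseSequence3D-class].
#' @param path File path.
#' @param stage Provenance tag (`"gt"`, `"raw"`, `"refined"`).
#' @export
writePoseCSV <- function(poses, path, stage = "gt") {
  lm <- poses@landmarkNames
  nF <- nFrames(poses)
  df <- data.frame(
    frame = rep(seq_len(nF), times = length(lm)),
    landmark = rep(lm, each = nF),
    x = as.vector(poses@positions[, , 1]),
    y = as.vector(poses@positions[, , 2]),
    z = as.vector(poses@positions[, , 3]),
    valid = as.vector(poses@valid),
    stage = stage)
  df <- df[order(df$frame, match(df$landmark, lm)), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @describeIn writePoseCSV Read a pose CSV back into a [PoseSequence3D-class].
#' @param fps Frame rate of the stored sequence.
#' @export
readPoseCSV <- function(path, fps = 30) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lm <- unique(df$landmark)
  nF <- max(df$frame)
  pos <- array(NA_real_, c(nF, length(lm), 3L))
  idx <- cbind(df$frame, match(df$landmark, lm))
  pos[cbind(idx, 1L)] <- df$x
  pos[cbind(idx, 2L)] <- df$y
  pos[cbind(idx, 3L)] <- df$z
  poseSequence(pos, landmarkNames = lm, fps = fps)
}
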