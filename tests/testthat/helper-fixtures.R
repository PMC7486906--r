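# Shared fixtures, built in code. Expensive objects are memoised per session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

fullRig <- function() memo("fullRig", makeRig(rigSpec()))

smallRig <- function() memo("smallRig", makeRig(rigSpec(nCameras = 12L)))

testSkeleton <- function() memo("skel", defaultSkeleton())

# A stereo pair looking down +z, 0.35 m baseline.
stereoPair <- function() list(
  cameraModel("a", 625, c(640, 512)),
  cameraModel("b", 625, c(640, 512), translation = c(-0.35, 0, 0)))

projectAll <- function(cameras, point) {
  t(vapply(cameras, function(cm) as.numeric(projectPoints(cm, point)),
           numeric(2)))
}

sixActionScript <- function(duration = 3) {
  motionScript(lapply(ACTION_LEVELS, function(a)
    list(action = a, duration = if (a == "jump") 1 else duration)))
}

# A short noisy walking sequence on the full rig with its raw
# reconstruction, shared by the refinement and ablation tests.
noisyWalkFixture <- function() {
  memo("noisyWalk", {
    rig <- fullRig()
    skel <- testSkeleton()
    mo <- simulateMotion(skel, motionScript(list(list(action = "walk", duration = 1.5))),
                         seed = 5)
    det <- emulateDetections(mo$poses, rig,
                             noiseModel(pixelSigma = 2, outlierProb = 0.1,
                                        missProb = 0.02, occlusion = TRUE,
                                        seed = 7))
    raw <- reconstructSequence(det, rig)
    list(rig = rig, skel = skel, mo = mo, det = det, raw = raw)
  })
}

# Mean 3D landmark error of a reconstruction vs ground truth.
mean3dError <- function(pred, ref) {
  mean(sqrt(rowSums((matrix(pred@positions, ncol = 3L) -
                       matrix(ref@positions, ncol = 3L))^2)), na.rm = TRUE)
}

# Per-edge temporal standard deviation of limb lengths.
limbLengthSds <- function(poses, skel) {
  e <- skeletonEdges(skel)
  vapply(seq_len(nrow(e)), function(i)
    stats::sd(sqrt(rowSums((poses@positions[, e[i, 1], ] -
                              poses@positions[, e[i, 2], ])^2)), na.rm = TRUE),
    numeric(1))
}

# Independent brute-force PCK oracle: plain loops, no shared code with pck3d.
bruteForcePCK <- function(pred, ref, tol) {
  lm <- ref@landmarkNames
  per <- numeric(0)
  for (l in lm) {
    hits <- 0L; total <- 0L
    for (f in seq_len(nFrames(ref))) {
      if (!poseValid(ref)[f, l]) next
      total <- total + 1L
      if (!poseValid(pred)[f, l]) next
      d <- sqrt(sum((posePositions(pred)[f, l, ] - posePositions(ref)[f, l, ])^2))
      if (d <= tol) hits <- hits + 1L
    }
    per[l] <- if (total) hits / total else NA_real_
  }
  list(perLandmark = per, overall = mean(per, na.rm = TRUE))
}

# A matched pair of partially valid random sequences for PCK oracle checks.
randomPoseSequences <- function(seed, nF = 25L) {
  set.seed(seed)
  lm <- landmarkNames(testSkeleton())
  pos <- array(rnorm(nF * 13 * 3, 0, 0.5), c(nF, 13, 3))
  valid <- matrix(runif(nF * 13) > 0.15, nF, 13)
  pos[rep(!valid, 3)] <- NA
  ref <- poseSequence(pos, valid = valid, landmarkNames = lm, fps = 30)
  pos2 <- posePositions(ref) + array(rnorm(nF * 13 * 3, 0, 0.08), c(nF, 13, 3))
  valid2 <- poseValid(ref) & matrix(runif(nF * 13) > 0.1, nF, 13)
  pos2[rep(!valid2, 3)] <- NA
  pred <- poseSequence(pos2, valid = valid2, landmarkNames = lm, fps = 30)
  list(pred = pred, ref = ref)
}

# 2D single-rotating-camera features: frame f seen through camera (f mod n)+1.
rotatingCameraFeatures <- function(mo, rig, skel) {
  nF <- nFrames(mo$poses)
  out <- matrix(NA_real_, nF, 2L * length(landmarkNames(skel)))
  for (f in seq_len(nF)) {
    cam <- rig[[(f %% length(rig)) + 1L]]
    p <- poseFrame(mo$poses, f)
    px <- projectPoints(cam, p, clipBehind = TRUE)
    rownames(px) <- rownames(p)
    if (any(!is.finite(px))) next
    out[f, ] <- vectorize2D(px, skel)
  }
  out
}
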