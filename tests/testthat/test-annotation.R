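# Fixture: one standing frame on the full rig with exact annotations in a few
# views.
standingFixture <- function() {
  memo("standingFixture", {
    rig <- fullRig()
    mo <- simulateMotion(script = motionScript(list(list(action = "stand", duration = 0.2))),
                         seed = 2)
    pose <- poseFrame(mo$poses, 3)
    ids <- vapply(rig, cameraId, character(1))
    annotate <- function(viewIds) {
      rows <- do.call(rbind, lapply(viewIds, function(v) {
        cm <- rig[[match(v, ids)]]
        px <- projectPoints(cm, pose)
        data.frame(frame = 3L, camera_id = v, landmark = rownames(pose),
                   x = px[, 1], y = px[, 2])
      }))
      annotationSet(rows, landmarkNames = rownames(pose))
    }
    list(rig = rig, pose = pose, ids = ids, annotate = annotate)
  })
}

test_that("center-of-mass triangulation matches the landmark centroid", {
  rig <- fullRig()
  mo <- simulateMotion(script = motionScript(list(list(action = "walk", duration = 0.2))),
                       seed = 3)
  cen <- emulateCentroids(mo$poses, rig,
                          noiseModel(pixelSigma = 0, outlierProb = 0,
                                     missProb = 0, occlusion = FALSE, seed = 1))
  com <- centerOfMass3D(cen[cen$frame == 2, ], rig)
  expect_true(com$valid)
  expect_lt(sqrt(sum((com$point - colMeans(poseFrame(mo$poses, 2)))^2)), 0.05)
  # a single view cannot triangulate
  one <- centerOfMass3D(cen[cen$frame == 2, ][1, ], rig)
  expect_false(one$valid)
})

test_that("center of mass is robust to a minority of outlier centroids", {
  rig <- fullRig()
  mo <- simulateMotion(script = motionScript(list(list(action = "sit", duration = 0.1))),
                       seed = 4)
  clean <- emulateCentroids(mo$poses, rig,
                            noiseModel(pixelSigma = 0, outlierProb = 0,
                                       missProb = 0, occlusion = FALSE, seed = 1))
  f1 <- clean[clean$frame == 1, ]
  ref <- centerOfMass3D(f1, rig)$point
  set.seed(5)
  bad <- sample(nrow(f1), round(0.2 * nrow(f1)))
  f1$x[bad] <- runif(length(bad), 0, 1279)
  f1$y[bad] <- runif(length(bad), 0, 1023)
  rob <- centerOfMass3D(f1, rig)
  expect_true(rob$valid)
  expect_lt(sqrt(sum((rob$point - ref)^2)), 0.05)
})

test_that("keyframe selection follows cumulative displacement", {
  # stationary trajectory: only the first frame
  com <- matrix(rep(c(0.1, 0.2, 0.5), each = 100), ncol = 3)
  expect_identical(selectKeyframes(com), 1L)
  # zero threshold retains every frame
  com2 <- matrix(cumsum(rep(0.01, 60)), 60, 3)
  expect_identical(selectKeyframes(com2, 0), seq_len(60L))
  # keyframe count is monotone non-increasing in the threshold
  set.seed(6)
  walkCom <- apply(matrix(rnorm(300, 0, 0.05), 100, 3), 2, cumsum)
  counts <- vapply(c(0, 0.05, 0.1, 0.2, 0.5),
                   function(th) length(selectKeyframes(walkCom, th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("keyframes concentrate in the dynamic segment of a sit-jump-sit script", {
  mo <- simulateMotion(script = motionScript(list(
    list(action = "sit", duration = 10),
    list(action = "jump", duration = 1),
    list(action = "sit", duration = 10))), seed = 8)
  com <- t(vapply(seq_len(nFrames(mo$poses)), function(f)
    colMeans(poseFrame(mo$poses, f)), numeric(3)))
  kf <- selectKeyframes(com, 0.15)
  expect_identical(kf[1], 1L)
  jumpWindow <- 300:332  # scripted jump frames plus landing transition
  expect_true(all(kf[-1] %in% jumpWindow))
  expect_gt(length(kf), 3L)
})

test_that("crop windows shrink inversely with distance", {
  cam <- cameraModel("c", 780, c(639.5, 511.5))
  w3 <- cropWindow(c(0, 0, 3), cam, scaleConst = 780)
  w6 <- cropWindow(c(0, 0, 6), cam, scaleConst = 780)
  expect_equal(w3$side, 2 * w6$side, tolerance = 1e-12)
  # anchored: ~150 px at 5.2 m implies ~260 px at 3 m
  w52 <- cropWindow(c(0, 0, 5.2), cam, scaleConst = 780)
  expect_equal(w52$side, 150, tolerance = 1e-9)
  expect_equal(w3$side, 260, tolerance = 1e-9)
  expect_error(cropWindow(c(0, 0, -1), cam), "behind-camera")
})

test_that("clipped crops stay inside the image for enclosure-interior points", {
  rig <- fullRig()
  pts <- expand.grid(x = c(-0.8, 0, 0.8), y = c(-0.8, 0, 0.8), z = c(0.4, 1.2, 2))
  for (cm in rig[seq(1, 62, by = 9)]) {
    for (i in seq_len(nrow(pts))) {
      p <- as.numeric(pts[i, ])
      if (poseRig::pointDepth(cm, p) <= 0.3) next
      w <- cropWindow(p, cm)
      expect_gte(w$center[1] - w$side / 2, -0.51)
      expect_lte(w$center[1] + w$side / 2, 1279.51)
      expect_gte(w$center[2] - w$side / 2, -0.51)
      expect_lte(w$center[2] + w$side / 2, 1023.51)
    }
  }
})

test_that("crop/image coordinate maps are mutually inverse", {
  crop <- cropWindow(c(0.3, -0.2, 1.5), fullRig()[[5]])
  px <- cbind(runif(20, 0, 367), runif(20, 0, 367))
  expect_lt(max(abs(imageToCrop(crop, cropToImage(crop, px)) - px)), 1e-9)
})

test_that("view proposal picks maximally separated visible cameras", {
  # four cameras at square corners, looking at the center: k = 2 gives a
  # diagonal pair
  mk <- function(id, x, y) {
    R <- poseRig:::lookAtRotation(c(x, y, 1), c(0, 0, 1))
    cameraModel(id, 780, c(639.5, 511.5), rotation = R,
                translation = as.numeric(-R %*% c(x, y, 1)))
  }
  sq <- list(mk("a", 2, 2), mk("b", -2, 2), mk("c", -2, -2), mk("d", 2, -2))
  sel <- proposeAnnotationViews(c(0, 0, 1), sq, k = 2)
  expect_setequal(sel, switch(sel[1], a = , c = c("a", "c"), c("b", "d")))
  # k equal to all visible: everything comes back (with a warning when fewer)
  expect_setequal(proposeAnnotationViews(c(0, 0, 1), sq, k = 4),
                  c("a", "b", "c", "d"))
  expect_warning(proposeAnnotationViews(c(0, 0, 1), sq, k = 5), "fewer than k")
})

test_that("proposed rig views are well separated", {
  fx <- standingFixture()
  sel <- proposeAnnotationViews(colMeans(fx$pose), fx$rig, k = 3)
  ctrs <- t(vapply(fx$rig, cameraCenter, numeric(3)))
  selC <- ctrs[match(sel, fx$ids), ]
  dsel <- min(dist(selC))
  allPairs <- as.numeric(dist(ctrs))
  expect_gte(dsel, stats::quantile(allPairs, 0.25))
})

test_that("geometric verification flags exactly the corrupted annotation", {
  fx <- standingFixture()
  views <- proposeAnnotationViews(colMeans(fx$pose), fx$rig, k = 3)
  ann <- fx$annotate(views)
  v <- verifyAnnotations(ann, fx$rig)
  expect_true(all(v$report$verifiable))
  expect_lt(max(v$report$error_px), 1e-6)
  expect_false(any(v$report$flagged))
  # shift one view's left_hand by 50 px: exactly that entry gets flagged
  rec <- annotationRecords(ann)
  j <- which(rec$camera_id == views[1] & rec$landmark == "left_hand")
  rec$x[j] <- rec$x[j] + 50
  v2 <- verifyAnnotations(annotationSet(rec, rownames(fx$pose)), fx$rig)
  fl <- v2$report[v2$report$flagged, ]
  expect_identical(nrow(fl), 1L)
  expect_identical(fl$camera_id, views[1])
  expect_identical(fl$landmark, "left_hand")
  # the gate sits at 10 px: a 9 px shift must pass
  rec3 <- annotationRecords(ann)
  rec3$x[j] <- rec3$x[j] + 9
  v3 <- verifyAnnotations(annotationSet(rec3, rownames(fx$pose)), fx$rig)
  expect_false(any(v3$report$flagged[v3$report$landmark == "left_hand" &
                                       v3$report$camera_id != views[1]]))
  # a landmark seen in one view only is unverifiable, not flagged
  rec4 <- annotationRecords(ann)
  rec4 <- rec4[!(rec4$landmark == "tail" & rec4$camera_id != views[1]), ]
  v4 <- verifyAnnotations(annotationSet(rec4, rownames(fx$pose)), fx$rig)
  tailRep <- v4$report[v4$report$landmark == "tail", ]
  expect_false(any(tailRep$verifiable))
  expect_false(any(tailRep$flagged))
})

test_that("propagation reproduces ground-truth projections and amplifies labels", {
  fx <- standingFixture()
  views <- proposeAnnotationViews(colMeans(fx$pose), fx$rig, k = 3)
  ann <- verifyAnnotations(fx$annotate(views), fx$rig)$annotations
  prop <- propagateLabels(ann, fx$rig)
  rec <- annotationRecords(prop)
  sub <- rec[rec$source == "propagated", ]
  expect_gt(nrow(sub), 0)
  for (i in sample(nrow(sub), 40)) {
    cm <- fx$rig[[match(sub$camera_id[i], fx$ids)]]
    gt <- projectPoints(cm, fx$pose[sub$landmark[i], ])
    expect_lt(max(abs(gt - c(sub$x[i], sub$y[i]))), 1e-6)
  }
  # amplification ~ 20x with 3 annotated views on a 62-camera rig
  amp <- amplificationFactor(prop)
  expect_gt(amp, 12)
  expect_lte(amp, 62 / 3)
  # amplification is exactly (#labeled views) / (#annotated views) per landmark
  perLm <- table(rec$landmark) / 3
  expect_equal(unname(amp), mean(perLm), tolerance = 1e-12)
})

test_that("propagating after verification is self-consistent and ignores flagged views", {
  fx <- standingFixture()
  views <- proposeAnnotationViews(colMeans(fx$pose), fx$rig, k = 4)
  ann <- fx$annotate(views)
  rec <- annotationRecords(ann)
  j <- which(rec$camera_id == views[2] & rec$landmark == "right_foot")
  rec$y[j] <- rec$y[j] + 80
  v <- verifyAnnotations(annotationSet(rec, rownames(fx$pose)), fx$rig)
  prop <- propagateLabels(v$annotations, fx$rig)
  # corrupted view was excluded: propagated labels still match ground truth
  pr <- annotationRecords(prop)
  sub <- pr[pr$source == "propagated" & pr$landmark == "right_foot", ]
  for (i in seq_len(nrow(sub))) {
    cm <- fx$rig[[match(sub$camera_id[i], fx$ids)]]
    gt <- projectPoints(cm, fx$pose["right_foot", ])
    expect_lt(max(abs(gt - c(sub$x[i], sub$y[i]))), 1e-6)
  }
  # re-verifying the human records after propagation yields no new flags
  v2 <- verifyAnnotations(prop, fx$rig)
  rep2 <- v2$report[!(v2$report$camera_id == views[2] &
                        v2$report$landmark == "right_foot"), ]
  expect_false(any(rep2$flagged))
})

test_that("the affine family has exactly nine members with exact arithmetic", {
  skel <- testSkeleton()
  labels <- matrix(runif(26, 50, 300), 13, 2,
                   dimnames = list(landmarkNames(skel), NULL))
  fam <- affineAugment(labels, skel@bilateralPairs)
  expect_length(fam, 9L)
  expect_setequal(names(fam), c("rot_p30", "rot_m30", "shift_left",
                                "shift_right", "shift_up", "shift_down",
                                "scale_110", "scale_090", "hflip"))
  # horizontal flip mirrors x and swaps bilateral labels
  lab2 <- labels
  lab2["left_hand", ] <- c(10, 20)
  fam2 <- affineAugment(lab2, skel@bilateralPairs)
  expect_equal(unname(fam2$hflip$labels["right_hand", ]), c(357, 20))
  # +30 then -30 degrees is the identity
  r1 <- fam$rot_p30$labels
  back <- affineAugment(r1, skel@bilateralPairs)$rot_m30$labels
  expect_lt(max(abs(back - labels)), 1e-9)
  # 20% shifts move labels by 73.6 px
  expect_equal(unname(fam$shift_right$labels[1, 1] - labels[1, 1]), 73.6)
  # out-of-crop labels are marked invalid
  labEdge <- labels; labEdge[1, ] <- c(360, 5)
  famE <- affineAugment(labEdge, skel@bilateralPairs)
  expect_false(famE$shift_right$valid[1])
})

test_that("keypoint JSON round-trips annotations with provenance", {
  fx <- standingFixture()
  views <- proposeAnnotationViews(colMeans(fx$pose), fx$rig, k = 3)
  ann <- verifyAnnotations(fx$annotate(views), fx$rig)$annotations
  prop <- propagateLabels(ann, fx$rig)
  path <- withr::local_tempfile(fileext = ".json")
  writeKeypointsJSON(prop, path)
  back <- readKeypointsJSON(path, as = "annotations")
  a <- annotationRecords(prop); b <- annotationRecords(back)
  key <- function(d) d[order(d$frame, d$camera_id, d$landmark), ]
  a <- key(a); b <- key(b)
  expect_equal(nrow(a), nrow(b))
  expect_identical(a$source, b$source)
  expect_lt(max(abs(a$x - b$x)), 1e-9)
  # detections round trip too
  det <- emulateDetections(simulateMotion(
    script = motionScript(list(list(action = "sit", duration = 0.1))),
    seed = 1)$poses, smallRig(), noiseModel(seed = 2))
  path2 <- withr::local_tempfile(fileext = ".json")
  writeKeypointsJSON(det, path2)
  det2 <- readKeypointsJSON(path2, as = "detections")
  r1 <- key2 <- detectionRecords(det)
  r2 <- detectionRecords(det2)
  r1 <- r1[order(r1$frame, r1$camera_id, r1$landmark), ]
  r2 <- r2[order(r2$frame, r2$camera_id, r2$landmark), ]
  expect_equal(nrow(r1), nrow(r2))
  expect_lt(max(abs(r1$x - r2$x)), 1e-9)
})
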