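test_that("canonical features are invariant to location, heading, and size", {
  skel <- testSkeleton()
  mo <- simulateMotion(skel, sixActionScript(0.5), seed = 20)
  set.seed(21)
  for (f in sample(nFrames(mo$poses), 12)) {
    p <- poseFrame(mo$poses, f)
    base <- canonicalize(p, skel)
    expect_length(base, 36L)
    th <- runif(1, 0, 2 * pi)
    R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
    s <- runif(1, 0.5, 2)
    tr <- c(runif(2, -1, 1), runif(1, -0.2, 0.2))
    p2 <- p %*% t(R) * s + matrix(tr, 13, 3, byrow = TRUE)
    rownames(p2) <- rownames(p)
    expect_lt(max(abs(canonicalize(p2, skel) - base)), 1e-9)
  }
})

test_that("canonical features are equivariant under left/right mirroring", {
  skel <- testSkeleton()
  mo <- simulateMotion(skel, motionScript(list(list(action = "walk", duration = 0.5))),
                       seed = 22, start = list(position = c(0, 0), headingDeg = 0))
  p <- poseFrame(mo$poses, 8)
  # mirror across the world xz-plane (contains gravity and the heading)
  pm <- p; pm[, 2] <- -pm[, 2]
  # swap bilateral labels on the mirrored body
  for (i in seq_len(nrow(skel@bilateralPairs))) {
    a <- skel@bilateralPairs[i, 1]; b <- skel@bilateralPairs[i, 2]
    tmp <- pm[a, ]; pm[a, ] <- pm[b, ]; pm[b, ] <- tmp
  }
  fa <- matrix(canonicalize(p, skel), ncol = 3, byrow = TRUE)
  fb <- matrix(canonicalize(pm, skel), ncol = 3, byrow = TRUE)
  lmOut <- setdiff(landmarkNames(skel), "neck")
  rownames(fa) <- rownames(fb) <- lmOut
  # mirrored feature: x negated, bilateral rows swapped
  fexp <- fa; fexp[, 1] <- -fexp[, 1]
  for (i in seq_len(nrow(skel@bilateralPairs))) {
    a <- skel@bilateralPairs[i, 1]; b <- skel@bilateralPairs[i, 2]
    tmp <- fexp[a, ]; fexp[a, ] <- fexp[b, ]; fexp[b, ] <- tmp
  }
  expect_lt(max(abs(fb - fexp)), 1e-9)
})

test_that("canonicalization normalizes the spine and handles degenerate poses", {
  skel <- testSkeleton()
  mo <- simulateMotion(skel, motionScript(list(list(action = "stand", duration = 0.1))),
                       seed = 23)
  p <- poseFrame(mo$poses, 1)
  feat <- matrix(canonicalize(p, skel), ncol = 3, byrow = TRUE)
  rownames(feat) <- setdiff(landmarkNames(skel), "neck")
  expect_equal(sqrt(sum(feat["hip", ]^2)), 1, tolerance = 1e-9)
  # neck == hip is an error
  bad <- p; bad["hip", ] <- bad["neck", ]
  expect_error(canonicalize(bad, skel), "spine")
  # spine exactly parallel to gravity falls back to the shoulder axis
  vert <- p
  vert["hip", ] <- vert["neck", ] - c(0, 0, 0.35)
  expect_length(canonicalize(vert, skel), 36L)
})

test_that("the 2D representation keeps viewpoint and position information", {
  skel <- testSkeleton()
  px <- matrix(runif(26, 0, 1000), 13, 2,
               dimnames = list(landmarkNames(skel), NULL))
  v <- vectorize2D(px, skel)
  expect_length(v, 26L)
  expect_equal(vectorize2D(px * 0, skel), rep(0, 26))
  shifted <- px + 100
  expect_false(isTRUE(all.equal(vectorize2D(shifted, skel), v)))
  pxNA <- px; pxNA[3, 1] <- NA
  expect_error(vectorize2D(pxNA, skel), "all landmarks")
})

test_that("embedding and clustering recover the scripted actions", {
  skel <- testSkeleton()
  mo <- simulateMotion(skel, sixActionScript(2), seed = 24)
  feats <- canonicalizeSequence(mo$poses, skel)
  expect_false(anyNA(feats))
  ec <- embedAndCluster(feats, seed = 25)
  expect_equal(dim(ec$embedding), c(nrow(feats), 2L))
  # every point is labeled: the grouping is a partition
  expect_false(anyNA(ec$clusters))
  expect_gte(min(ec$clusters), 1L)
  ari <- mclust::adjustedRandIndex(ec$clusters,
                                   as.character(labelVector(mo$labels)))
  expect_gte(ari, 0.7)
  # determinism
  ec2 <- embedAndCluster(feats, seed = 25)
  expect_identical(ec$clusters, ec2$clusters)
})

test_that("degenerate feature sets are handled explicitly", {
  one <- matrix(1, 60, 36)
  ec <- embedAndCluster(one, seed = 1)
  expect_equal(unique(ec$clusters), 1L)
  expect_error(embedAndCluster(matrix(rnorm(36 * 10), 10), seed = 1),
               "at least 50")
})

test_that("kNN classification votes among neighbors with nearest tie-break", {
  train <- rbind(matrix(0, 5, 3), matrix(10, 5, 3))
  labs <- c(rep("sit", 5), rep("walk", 5))
  # exact training point with k = 1
  out <- classifyActions(train, labs, train[c(1, 8), , drop = FALSE], k = 1)
  expect_identical(as.character(labelVector(out)), c("sit", "walk"))
  # single-class training set gives constant output
  out2 <- classifyActions(train[1:5, ], labs[1:5],
                          matrix(rnorm(30), 10, 3), k = 3)
  expect_true(all(labelVector(out2) == "sit"))
  # even k with a 50/50 vote falls back to the nearest neighbor's label
  train3 <- rbind(c(0, 0, 0), c(1, 1, 1))
  out3 <- classifyActions(train3, c("sit", "walk"),
                          matrix(c(0.1, 0.1, 0.1), 1), k = 2)
  expect_identical(as.character(labelVector(out3)), "sit")
})

test_that("kNN on canonical features recovers held-out synthetic actions", {
  skel <- testSkeleton()
  tr <- simulateMotion(skel, sixActionScript(2), seed = 26)
  te <- simulateMotion(skel, sixActionScript(2), seed = 27)
  ftr <- canonicalizeSequence(tr$poses, skel)
  fte <- canonicalizeSequence(te$poses, skel)
  pred <- classifyActions(ftr, tr$labels, fte, k = 15)
  acc <- mean(labelVector(pred) == labelVector(te$labels))
  expect_gte(acc, 0.9)
})

test_that("transition matrices are row-stochastic and follow the script", {
  # constant labels: a single diagonal 1
  tm <- transitionMatrix(actionLabels(rep("sit", 50)))
  expect_equal(tm["sit", "sit"], 1)
  expect_equal(sum(tm), 1)
  # scripted transitions appear exactly where scripted
  labs <- c(rep("walk", 10), rep("stand", 10), rep("climb", 10),
            rep("climb_supine", 10))
  tm2 <- transitionMatrix(actionLabels(labs))
  nz <- which(tm2 > 0, arr.ind = TRUE)
  got <- paste(rownames(tm2)[nz[, 1]], colnames(tm2)[nz[, 2]], sep = ">")
  expect_setequal(got, c("walk>walk", "stand>stand", "climb>climb",
                         "climb_supine>climb_supine", "walk>stand",
                         "stand>climb", "climb>climb_supine"))
  rs <- rowSums(tm2)
  expect_true(all(abs(rs[rs > 0] - 1) < 1e-12))
})

test_that("two well-separated animals are tracked without identity swaps", {
  skel <- testSkeleton()
  rig <- smallRig()
  walkCfg <- list(straight = TRUE, speed = 0.35, jitter = 0.01)
  moA <- simulateMotion(skel, motionScript(list(list(action = "walk", duration = 3,
                                                     params = walkCfg))),
                        seed = 3, start = list(position = c(-0.55, -0.18),
                                               headingDeg = 0))
  moB <- simulateMotion(skel, motionScript(list(list(action = "walk", duration = 3,
                                                     params = walkCfg))),
                        seed = 4, start = list(position = c(0.55, 0.18),
                                               headingDeg = 180))
  nm <- function(s) noiseModel(pixelSigma = 2, outlierProb = 0, missProb = 0,
                               occlusion = FALSE, seed = s)
  cc <- rbind(emulateCentroids(moA$poses, rig, nm(5)),
              emulateCentroids(moB$poses, rig, nm(6)))
  cand <- centroidCandidates(cc, rig)
  tk <- trackTwoAnimals(cand, seed = 9)
  gtA <- t(vapply(seq_len(90), function(f) colMeans(poseFrame(moA$poses, f)),
                  numeric(3)))
  gtB <- t(vapply(seq_len(90), function(f) colMeans(poseFrame(moB$poses, f)),
                  numeric(3)))
  eAA <- sqrt(rowSums((tk$centersA - gtA)^2))
  eAB <- sqrt(rowSums((tk$centersA - gtB)^2))
  swapped <- sum(eAA > eAB, na.rm = TRUE)
  if (swapped == nrow(gtA)) {  # arbitrary initial naming; accept the mirror
    tmp <- eAA; eAA <- eAB; eAB <- tmp; swapped <- 0L
  }
  expect_identical(swapped, 0L)
  expect_false(any(tk$ambiguous))
  expect_lt(max(eAA, na.rm = TRUE), 0.1)
})

test_that("single-animal input with two requested centers is flagged degenerate", {
  cand <- lapply(1:5, function(f) matrix(rep(c(0.1, 0.2, 0.5), 4), 4, 3,
                                         byrow = TRUE))
  tk <- trackTwoAnimals(cand)
  expect_true(all(tk$degenerate))
})

test_that("static well-separated animals are assigned correctly every frame", {
  set.seed(30)
  a <- c(-0.6, 0, 0.5); b <- c(0.6, 0.3, 0.5)
  cand <- lapply(1:20, function(f)
    rbind(matrix(rnorm(30, 0, 0.01), 10, 3) + matrix(a, 10, 3, byrow = TRUE),
          matrix(rnorm(30, 0, 0.01), 10, 3) + matrix(b, 10, 3, byrow = TRUE)))
  tk <- trackTwoAnimals(cand, seed = 2)
  first <- tk$centersA[1, ]
  ref <- if (sqrt(sum((first - a)^2)) < sqrt(sum((first - b)^2))) a else b
  other <- if (identical(ref, a)) b else a
  expect_lt(max(sqrt(rowSums((tk$centersA - matrix(ref, 20, 3, byrow = TRUE))^2))), 0.05)
  expect_lt(max(sqrt(rowSums((tk$centersB - matrix(other, 20, 3, byrow = TRUE))^2))), 0.05)
})

test_that("co-occurrence counts are conserved and unbiased for independent streams", {
  a <- actionLabels(rep("walk", 25)); b <- actionLabels(rep("walk", 25))
  M <- cooccurrence(a, b)
  expect_equal(M["walk", "walk"], 25)
  expect_equal(sum(M), 25)
  expect_error(cooccurrence(a, actionLabels(rep("sit", 3))), "equal length")
  set.seed(31)
  n <- 10000
  la <- sample(ACTION_LEVELS, n, replace = TRUE)
  lb <- sample(ACTION_LEVELS, n, replace = TRUE)
  M2 <- cooccurrence(actionLabels(la), actionLabels(lb))
  expect_equal(sum(M2), n)
  p <- 1 / 36
  se <- sqrt(n * p * (1 - p))
  expect_true(all(abs(M2 - n * p) <= 3 * se))
  expect_equal(attr(M2, "log"), log1p(unclass(M2)[, ]), ignore_attr = TRUE)
})

test_that("proxemics concentrates mass where the conspecific actually is", {
  skel <- testSkeleton()
  mo <- simulateMotion(skel, motionScript(list(list(action = "stand", duration = 1))),
                       seed = 33, start = list(position = c(-0.5, 0), headingDeg = 0))
  # B exactly 1 m ahead of A (heading +x)
  pb <- mo$poses@positions
  pb[, , 1] <- pb[, , 1] + 1
  posesB <- poseSequence(pb, landmarkNames = landmarkNames(skel), fps = 30)
  ph <- proxemics(mo$poses, posesB, rEdges = seq(0, 3, 0.25),
                  thetaEdges = seq(-180, 180, 30))
  expect_equal(sum(ph$mass), 1)
  ahead <- ph$mass[4:5, 6:7]  # r in [0.75, 1.25), theta in [-30, 30)
  expect_gte(sum(ahead), 0.99)
})

test_that("proxemics bearing marginal is uniform for a uniformly placed conspecific", {
  skel <- testSkeleton()
  mo <- simulateMotion(skel, motionScript(list(list(action = "stand", duration = 8))),
                       seed = 34)
  nF <- nFrames(mo$poses)
  set.seed(35)
  th <- runif(nF, -pi, pi)
  pb <- mo$poses@positions
  pb[, , 1] <- pb[, , 1] + cos(th)
  pb[, , 2] <- pb[, , 2] + sin(th)
  posesB <- poseSequence(pb, landmarkNames = landmarkNames(skel), fps = 30)
  ph <- proxemics(mo$poses, posesB, rEdges = c(0, 2),
                  thetaEdges = seq(-180, 180, 60))
  counts <- ph$mass * ph$nUsed
  p <- 1 / 6
  se <- sqrt(ph$nUsed * p * (1 - p))
  expect_true(all(abs(counts - ph$nUsed * p) <= 3.5 * se))
})
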