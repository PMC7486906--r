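# poseRig

Markerless multiview motion capture for freely moving primates, in R.

Large-bodied primates such as rhesus macaques move through big
three-dimensional spaces using all four limbs, head, and tail, and they do not
tolerate markers, jackets, or head-mounted gear. The practical route to
full-body kinematics is therefore *markerless* capture: a dense ring of
calibrated cameras around the enclosure, a per-view landmark detector, and 3D
reconstruction by multiview geometry. `poseRig` implements the computational
core of such a system as a reusable library:

- **Camera geometry** — calibrated pinhole camera models with radial
  distortion, and three triangulators: direct linear transform (DLT),
  mean-shift mode seeking over pairwise candidates, and RANSAC (pairwise
  hypotheses validated by reprojection onto the remaining views).
- **Annotation efficiency** — keyframe selection by center-of-mass
  displacement, distance-adaptive crop windows, informative-view proposal,
  geometric verification of human annotations at a 10 px reprojection gate,
  and cross-view label propagation that turns a handful of annotated views
  into labels for the whole rig (a 15–20x amplification on a 62-camera rig),
  plus the nine-member affine augmentation family (±30° rotations, 20%
  shifts, ±10% scalings, horizontal flip with left/right label swap).
- **Plausible pose inference** — per-landmark RANSAC reconstruction,
  limb-length estimation by temporal medians, and kinematic-chain refinement
  that minimizes, per landmark `X_t` with parent `Y_t`,

  ```
  sum_i || Pi_i(X_t) - x_{i,t} ||^2
      + wL * ( ||X_t - Y_t|| - L_{X,Y} )^2
      + wT * || X_t - X_{t-1} ||^2
  ```

  by quasi-Newton descent, recursively from the neck down the kinematic tree
  and forward over frames (`Pi_i` is the projection into camera `i`,
  `x_{i,t}` the detection there, `L_{X,Y}` the estimated limb length).
- **Behavior analytics** — canonical body-centric features (neck origin,
  gravity y-axis, spine-aligned z-axis, unit spine length; 36 dimensions for
  13 landmarks), 2D embedding with cluster discovery, k-nearest-neighbor
  action classification, action transition matrices, two-animal tracking by
  k-means on triangulated centroid clouds, action co-occurrence, and
  proxemics (body-centric polar histograms of a conspecific's position).
- **Evaluation** — percentage of correct 3D keypoints (PCK@10 cm),
  camera-count ablations, view-dependent 2D accuracy profiles, and a
  configurable end-to-end pipeline driver.

Because trained detectors and multi-terabyte recordings do not fit in a
package, `poseRig` ships a **synthetic studio**: a 62-camera two-level rig
encircling a 2.45 × 2.45 × 2.75 m enclosure, an articulated 13-landmark
skeleton executing scripted actions (sit, stand, walk, climb, climb supine,
jump) with exactly conserved limb lengths, a detector emulator with Gaussian
pixel noise, gross outliers, misses and geometric torso occlusion, and
response-map rendering/decoding in the detector's 368-crop / 46-grid
conventions. Every operation in the package is exercised against this
simulator.

## Worked example

```r
library(poseRig)

skel <- defaultSkeleton()
rig  <- makeRig(rigSpec())          # 62 cameras, two rings, ~0.35 m baselines

script <- motionScript(list(
  list(action = "sit",  duration = 2),
  list(action = "walk", duration = 4)))
mo  <- simulateMotion(skel, script, seed = 1)

det <- emulateDetections(mo$poses, rig,
         noiseModel(pixelSigma = 2, outlierProb = 0.1, missProb = 0.02,
                    occlusion = TRUE, seed = 2))

raw  <- reconstructSequence(det, rig)          # per-landmark RANSAC
lens <- estimateLimbLengths(raw, skel)         # temporal medians
w    <- refineWeights(rig)                     # unit-consistent weights
ref  <- refineChain(raw, det, rig, skel, lens, wL = w$wL, wT = w$wT)

round(head(lens, 4), 4)
#>           nose           head  left_shoulder right_shoulder
#>         0.0900         0.1100         0.0999         0.1001

sc <- pck3d(ref, mo$poses)
sprintf("overall PCK@10cm: %.1f%%", 100 * sc$overall)
#> overall PCK@10cm: 100.0%
```

On this 180-frame sequence the mean 3D landmark error drops from 2.0 mm
(raw RANSAC) to 1.7 mm after kinematic refinement, and the estimated limb
lengths match the generator's rest lengths to well under a millimeter — the
landmark detections carried 2 px noise, 10% gross outliers, misses, and
torso occlusion. Canonical features of the refined poses classify held-out
frames of this clip at 100% accuracy with a k = 15 nearest-neighbor vote.

A full simulate → detect → reconstruct → refine → behavior → evaluate run
with artifacts on disk (pose CSVs, labels, metrics, plots, log):

```r
runPipeline(list(outDir = "out", seed = 1))
```

or from a shell, `inst/scripts/poserig run --config cfg.yaml`.

## Vignette

`vignettes/multiview-motion-capture.Rmd` describes the geometry, the
refinement objective and its weights, what the synthetic studio does and
does not emulate, the numerical choices (tolerances, tie-breaks, degenerate
cases), and known limitations.
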