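---
title: "Multiview markerless motion capture: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiview markerless motion capture: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poseRig)
```

`poseRig` reconstructs the 3D pose of a freely moving primate from
synchronized multi-camera 2D landmark observations, and turns the resulting
pose sequences into behavioral semantics. This vignette is the package's own
account of the underlying models: what is computed, under which assumptions,
which parameters matter, and where the design was genuinely open.

## 1. Camera model and triangulation

Each camera is a calibrated pinhole with two-term radial (Brown) distortion:
a world point $X$ maps to camera coordinates $X_c = R X + t$, is
perspective-divided, radially distorted with coefficients $(k_1, k_2)$, and
scaled by the intrinsics $(f_x, f_y, c_x, c_y)$. Pixels are 0-based and refer
to pixel centers; the world frame is metric, z-up, with the origin at the
enclosure floor center. The real system uses fisheye optics; the pinhole +
radial contract was adopted because every downstream computation is
projection-model-agnostic, and a fisheye (equidistant) projection could be
added behind the same `CameraModel` interface without touching the rest of
the package. Undistortion inverts the radial magnification by Newton
iteration on the radius, accurate below $10^{-9}$ px for $|k_1|, |k_2| \le
0.3$ across the image.

Three triangulators share this model:

* **DLT** stacks the homogeneous two-equations-per-view linear system on
  undistorted normalized observations and takes the SVD least-squares
  solution. A design-matrix condition number above $10^8$ (first to third
  singular value) signals degenerate, near-parallel geometry.
* **RANSAC** generates candidate points by closed-form two-view
  triangulation (midpoint of the common perpendicular of the two
  back-projected rays) and validates each candidate by reprojection onto all
  views; the candidate with the most inliers wins and the returned point is
  the DLT solution over its inliers. For up to 62 views *all* camera pairs
  are enumerated, which removes sampling variance entirely and makes the
  estimator deterministic; beyond that a seeded RNG draws pairs. The inlier
  gate defaults to 10 px, deliberately the same threshold used to verify
  human annotations. With zero outliers the procedure reduces exactly — bit
  for bit — to DLT over all views.
* **Mean-shift** triangulates all pairs and mode-seeks over the candidate
  cloud with a Gaussian kernel. The bandwidth is not specified by any
  reference we follow; the 0.05 m default is our choice, roughly half a
  torso radius, and as the bandwidth grows the mode tends to the candidate
  cloud's mean (the flat-kernel limit).

## 2. The synthetic studio

The package must be exercisable without terabytes of recordings or a trained
network, so it generates everything the real system records.

**Rig.** 62 cameras on two horizontal rings encircling a
$2.45 \times 2.45 \times 2.75$ m enclosure, every optical axis through the
enclosure center. The ring radius is set so adjacent same-level cameras sit
0.35 m apart — the spacing of a 16-per-wall layout — which bounds the
adjacent-camera viewing-angle difference at a 3 m subject by
$2 \arcsin(0.35/6) \approx 6.7^\circ$: the appearance change between
neighboring views is nearly continuous, which is what makes cross-view label
propagation and redundant triangulation work. Rings are staggered by half a
spacing; cameras near the enclosure corners sit at $\approx 45^\circ$ azimuth
automatically because they face the center. Intrinsics (focal 780 px,
$1280 \times 1024$) are chosen so a 1 m subject at the far diagonal
($\approx 5.2$ m) spans $\approx 150$ px.

**Skeleton and motion.** The 13-landmark set (nose, head, neck, shoulders,
hands, hip, knees, feet, tail) is rooted at the neck — the most reliably
reconstructed landmark — with rest limb lengths sized to an adult macaque.
No authoritative enumeration of the 13 landmarks exists for the system we
model, so the set is configurable through `skeleton()`; hands and feet
stand in for the distal forelimb/hindlimb points, and all tests run on this
default. Poses are composed by forward kinematics from unit direction
vectors, so limb lengths are conserved *exactly* in every generated frame —
that exactness is what lets the limb-length tests assert recovery rather
than approximation. Six action primitives (sit, stand, walk, climb,
climb-supine, jump) are parameterized by speed, gait frequency, and heading
wander; jumps are ballistic with $g = 9.81\ \mathrm{m/s^2}$, walking is a
sinusoidal contralateral gait. The primitives make no claim of biomechanical
fidelity; their adequacy criterion is that the actions be geometrically
distinct in canonical feature space, mirroring the separability of real
behavioral clusters.

**Detector emulation.** Per (frame, camera, landmark) the emulator emits,
with probability `missProb`, nothing; else with probability `outlierProb` a
uniform in-image pixel; else the exact projection plus per-axis
$\mathcal{N}(0, \sigma^2)$ noise. Landmarks projecting outside the image or
behind the camera are misses. With occlusion on, a landmark whose sight ray
passes through the torso capsule (neck–hip segment, radius 0.12 m — a
plumbing choice sized to macaque morphology) clearly *before* reaching the
landmark becomes a miss; the ray is extended beyond the landmark in this
test so that landmarks sitting on the torso surface (head, shoulders) do not
occlude themselves. Occlusion applies to genuine detections only — gross
outliers are hallucinations and fire regardless. The default noise
($\sigma = 2$ px, 10% outliers, 2% misses, occlusion on) is the study
condition for all end-to-end checks; what it does **not** emulate is
appearance: correlated errors from fur texture, lighting, motion blur, or
systematic detector bias. Passing tests therefore demonstrate the geometry
and robustness machinery, not detector quality on real images.

**Response maps.** Ground-truth detector targets are Gaussian bumps on a
$46 \times 46$ grid over a $368 \times 368$ crop (stride 8), 13 landmark
channels plus one background channel $\max(0, 1 - \max_l m_l)$. Decoding
takes the argmax cell back through the cell-center convention
(cell $g \mapsto 8g + 4$), so a render–decode round trip is exact to one
grid cell (8 crop px). Out-of-crop landmarks render as all-zero maps, the
occluded-label convention.

## 3. Annotation efficiency

The annotation machinery reproduces the bookkeeping that makes large-scale
labeling affordable:

* **Keyframes** are frames whose center of mass moved more than a threshold
  since the *last retained keyframe*. Whether the displacement should be
  frame-to-frame or cumulative was left open by our sources; we chose
  cumulative-to-last-keyframe so that slow drift accumulates and sustained
  locomotion is sampled at regular spatial intervals, and the default
  threshold of 0.15 m is set so quiescent sitting (sub-centimeter jitter)
  contributes a single keyframe. Keyframe count is monotone non-increasing
  in the threshold.
* **Crop windows** are centered on the projected center of mass with side
  inversely proportional to camera distance. The proportionality constant
  defaults to 1400 px·m so a 1 m subject fills ≈55% of the crop — margin for
  outstretched limbs; windows are clamped inside the image.
* **View proposal** replaces a human-in-the-loop choice with a greedy
  max-min rule: start from the camera seeing the center of mass most
  centrally, then repeatedly add the visible camera whose minimum
  optical-center distance to the selected set is largest (maximal baselines,
  minimal redundancy).
* **Verification** robustly triangulates each landmark from its human
  annotations and flags any annotation whose reprojection error exceeds
  10 px. The triangulation is the RANSAC estimator rather than a plain DLT:
  with a plain least-squares fit a single corrupted view drags the solution
  and spreads residuals across the good views, whereas the robust fit
  isolates exactly the corrupted entry — which is the point of geometric
  verification.
* **Propagation** triangulates each verified landmark from its unflagged
  views and projects it into every other camera where it lands in-image
  with positive depth. Labels are *occlusion-agnostic*: a torso-hidden
  landmark still receives its projected label, which is what teaches a
  detector to predict occluded joints from spatial configuration. On the
  default rig, three annotated views propagate to ≈58 others, an
  amplification of 15–20 depending on visibility, and the factor equals
  (#visible views)/(#annotated views) exactly when all propagations succeed.

## 4. Plausible pose inference

Raw reconstruction triangulates every (frame, landmark) independently with
RANSAC; entries with fewer than two observing views, or no consensus pair,
are flagged invalid rather than fatal. Limb lengths are then estimated as
temporal medians of inter-landmark distances — robust to a minority of
spurious frames — and the refinement minimizes, per landmark and frame,

$$\sum_i \lVert \Pi_i(X_t) - x_{i,t} \rVert^2
  + w_L \left( \lVert X_t - Y_t \rVert - L_{X,Y} \right)^2
  + w_T \lVert X_{t-1} - X_t \rVert^2$$

by BFGS with analytic gradients, from the raw estimate, to relative
tolerance $10^{-5}$. The recursion runs down the kinematic chain — the neck
(root) first, without the limb term, then each child against its
already-refined parent in breadth-first order (neck → hip/shoulders/head →
knees/hands/nose → feet/tail) — and sweeps frames forward so $X_{t-1}$ is
the already-refined value; at $t = 1$ the smoothness term is dropped. The
source formulation is a recursion over the chain and silent about time;
the forward sweep is the reading consistent with its $X_{t-1}$ dependence,
and it keeps the solver online (each frame solved once).

Numerical choices worth knowing:

* **Outlier gating.** The reprojection term sums over *gated* detections:
  observations reprojecting farther than the RANSAC gate (10 px) from the
  initialization are excluded. Without this, a single gross outlier
  dominates the squared loss and drags the refined point arbitrarily far.
* **Weights.** The printed objective is an unweighted sum, but its terms are
  dimensionally heterogeneous (pixels² vs meters²), so with $w_L = w_T = 1$
  the physical cues are numerically negligible against a 40-view pixel
  term. The defaults remain 1 to match the plain form; `refineWeights()`
  returns the unit-consistent scaling $w_L = n_\mathrm{views} (f/d)^2$,
  $w_T = 0.2 (f/d)^2$ (meters-to-pixels conversion at a typical subject
  distance $d \approx 2$ m, temporal cue down-weighted because genuine
  inter-frame motion at 30 fps exceeds per-frame reconstruction noise by an
  order of magnitude). Under that scaling, refinement reduces the temporal
  variance of every limb length and the mean 3D error at 1, 2, and 4 px
  noise on the default rig.
* **Gaps.** An invalid raw entry is re-initialized from the refined parent
  plus a rest-length offset along the previous frame's limb direction; with
  no parent information it stays invalid. The objective is audited to be
  non-increasing relative to initialization for every subproblem.
* **Hard gate.** Whether limb-length thresholds also act as hard accept/
  reject criteria, in addition to the soft penalty, was ambiguous in our
  sources; the soft penalty is the default and `gateByLimbLength()`
  (reject beyond 50% relative deviation) is available separately.

## 5. Behavior analytics

**Canonical features.** Each pose is expressed in a body-centric frame: neck
at the origin, canonical $y$ along gravity (world $+z \mapsto -y$, a
documented axis convention), canonical $z$ the horizontal (Gram–Schmidt)
projection of the neck→hip spine axis, $x = y \times z$, all coordinates
divided by spine length. Dropping the neck leaves a 36-vector for 13
landmarks, invariant to location, heading, and size, and equivariant under
left/right mirroring. If the spine is parallel to gravity the heading falls
back to the horizontal perpendicular of the shoulder axis (right-handed) — a
documented tie-break that matters for perfectly upright postures.

**Embedding and grouping.** The canonical features are reduced to two
dimensions and grouped. We use a deterministic principal-component
projection with a fixed sign convention, and Gaussian-mixture model
selection (BIC over 1–9 components) on the embedding, which discovers the
number of groups from density structure rather than taking it as input; the
entire path is deterministic given the seed. On scripted six-action
sequences the discovered clusters agree with the generating actions
(adjusted Rand index ≥ 0.95 in the packaged runs). Identical feature sets
short-circuit to a single cluster. Nonlinear neighbor-embedding methods
(UMAP and relatives) serve the same role in the wider literature; the
PCA-plus-mixture pipeline was chosen here for determinism and zero
additional dependencies, and the clustering contract (`embedAndCluster()`)
would accept any embedding backend.

**Classification, transitions, social measures.** Actions in new sequences
are classified by a $k = 15$ (odd, majority-vote) nearest-neighbor rule in
canonical feature space, ties broken by the single nearest neighbor; no
reference value of $k$ exists, and accuracy on synthetic episodes is flat
for $k$ between 5 and 31. The deliberately view-contaminated 26-dimensional
2D baseline (raw pixel coordinates from one rotating camera, no
normalization) scores consistently lower — the packaged acceptance run
prints the two numbers side by side. Transition matrices are
consecutive-frame counts with row normalization (zero rows stay zero).
Two-animal tracking k-means (k = 2) the per-frame cloud of
geometrically consistent pairwise centroid triangulations (mixed-identity
"ghost" pairs are rejected because their rays are skew by more than 5 cm),
carries identity by nearest-neighbor matching of centers (swapping only if
that lowers the total distance), and flags frames with centers closer than
0.15 m as ambiguous — a stand-in for whatever appearance-based identity a
real system would add. Proxemics histograms the conspecific's neck position
in the focal animal's body-centric polar frame (facing direction = horizontal
neck→nose, counter-clockwise positive, shoulder-axis fallback), normalized
to unit mass.

## 6. Evaluation protocols

PCK@10 cm is the fraction of (frame, landmark) instances within tolerance
of the reference; landmarks without comparable instances are excluded from
the overall mean, and a predicted-invalid entry against a valid reference
counts as incorrect. Camera-count ablations reconstruct from evenly spaced
azimuth-ordered subsets (deterministic; the azimuth ordering interleaves the
two staggered rings) and score against either the full-rig reconstruction
(relative accuracy, as when no ground truth exists) or the synthetic ground
truth. View-dependent accuracy bins per-detection pixel errors by the signed
horizontal camera angle relative to the facing direction (negative = left).

**Problem sizes.** The packaged tests and the acceptance script run the
default study conditions at desk scale: 45–300-frame sequences, 100-trial
robustness sweeps, 3–5 seeds per stochastic experiment. These sizes were
chosen so the complete suite executes in a few minutes on one CPU while
leaving every Monte-Carlo margin wide (e.g. the RANSAC robustness check
passes 100/100 trials against a ≥99 requirement).

## 7. Known limitations

* The detector emulator's errors are independent across views and frames;
  real detector errors are correlated (same fur, same pose ambiguity from
  nearby views), so real-data accuracy will be lower than the synthetic
  numbers at equal noise magnitude.
* The pinhole + radial model will not fit strongly fisheye optics without an
  equidistant extension.
* The action primitives are geometric, not biomechanical; classifier
  accuracies on them measure representation quality, not ethological
  validity.
* Two-animal tracking has no appearance model; sustained contact (centers
  within the ambiguity radius for many frames) cannot be disambiguated from
  geometry alone.
* Calibration is consumed, never estimated: structure-from-motion, wanding,
  and rolling-shutter effects are out of scope.
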