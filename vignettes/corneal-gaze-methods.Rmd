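---
title: "Calibration-free gaze estimation by corneal imaging: models and methods"
author: "CornealGaze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibration-free gaze estimation by corneal imaging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CornealGaze)
```

# The problem

A head-mounted eye tracker normally needs a per-user calibration ritual
(fixating markers) and needs it again every time the headset shifts.
Corneal imaging removes the ritual: the tear film makes the cornea a convex
mirror, so an RGB camera pointed at the eye sees a small reflected copy of
the scene the user is looking at, with the pupil centre marking the gaze
point inside that reflection. Matching the reflected content against a
front-facing scene camera ties the pupil centre to a scene location without
the user doing anything.

The rig has three cameras: an IR eye camera (800 x 600; the pupil is crisp
under IR illumination), an RGB eye camera (1280 x 960; carries the corneal
reflection, but the pupil itself is often washed out by that same
reflection), and a front scene camera (1280 x 960). The pipeline is:

1. detect the pupil in the IR image;
2. map the detection point-to-point into the RGB eye image through a
   per-user 3D eyeball model;
3. crop the corneal patch around the mapped pupil and mirror it to world
   orientation;
4. transfer the pupil centre into the scene image with a homography
   estimated from feature matches between corneal patches and scene images.

Steps 2 and 4 are auto-calibrated from natural viewing. Stereo extrinsics
between the two eye cameras and all intrinsics are one-time offline inputs
(chessboard calibration; consumed from a JSON/YAML file, never estimated
here).

# The eyeball model

The eyeball is a sphere of fixed anatomical radius $r = 12$ mm; only its
centre $\mathbf{c}$ (in the IR-camera frame, the world frame of all
eye-side geometry) is estimated per user. During calibration, pupil
boundary points are detected in timestamp-paired IR/RGB frames, put in
correspondence, and each pair is triangulated: two backprojected rays are
generally skew, so the 3D point is the midpoint of their common
perpendicular, and the length of that segment (the *gap*) gates bad
correspondences (default `gapMax` 2 mm). The resulting points
$\mathbf{p}_i$ lie on the eyeball surface, so the centre solves

$$\min_{\mathbf{c}} \sum_i \left( \lVert \mathbf{p}_i - \mathbf{c} \rVert - 12 \right)^2 .$$

This is solved by Gauss-Newton with the analytic Jacobian
$\partial r_i / \partial \mathbf{c} = -(\mathbf{p}_i - \mathbf{c}) / \lVert \mathbf{p}_i - \mathbf{c} \rVert$,
initialized at the point mean pushed 12 mm along the mean viewing
direction; a Nelder-Mead fallback handles non-convergence. The fitted
`rmsResidual` is stored with the model.

With the model in hand, an IR pixel maps to an RGB pixel point-to-point
(not point-to-line as a fundamental matrix would): backproject the IR
pixel, intersect the ray with the sphere, and reproject the 3D point into
the RGB camera. The quadratic $\lVert \mathbf{o} + t\mathbf{d} - \mathbf{c} \rVert^2 = r^2$
has two roots; the near root is always taken because a visible pupil must
sit on the camera-facing hemisphere. The 3D gaze ray (the *optical axis*)
runs from the eyeball centre through the pupil-centre surface point; the
per-person kappa offset to the visual axis is not corrected, matching what
the geometry alone can deliver.

## Boundary correspondence

How IR and RGB boundary points are put in correspondence is genuinely open
(reflections corrupt the RGB boundary in real data). The package pairs
points at equal parameter angle on the two fitted ellipses
(`makeCorrespondences`). Equal angles do not label physically identical
limbus points, but the sphere fit only needs points *on the surface*, which
any crossing of the two rays near the eye delivers; the `gapMax` gate
rejects pairings whose rays pass far apart.

# Corneal patch and gaze transfer

The IR bounding box is mapped corner-by-corner into the RGB image, grown by
a 10% margin (features just outside the pupil boundary are useful), clipped
to the frame, cropped, and mirrored horizontally — a convex reflector
mirrors a roughly frontal scene about the vertical axis; the flip direction
is configurable for unusual mounts. The pupil centre rides along into
crop-local coordinates as the `gazePoint`. Whether to flip before or after
feature extraction is unstated territory; this package always flips first,
so corneal-patch content is world-oriented everywhere downstream.

Corner features (multi-scale Harris + normalized intensity patches, Lowe
ratio test 0.75) are matched between the corneal patch and the scene image.
The scale gap between the minified reflection and the scene is handled by
matching against a small scene pyramid and keeping the best-supported
level; both images are pre-smoothed (sigma 1.5 px) so the patch descriptors
tolerate the reflection's blur and resolution loss. This is a classical
corner/patch matcher written for this package; it honours the same module
contract as any scale-invariant descriptor pipeline, and a different
matcher can be dropped in behind `detectAndMatch`.

The corneal-to-scene map is a homography $H$ (exact for a planar scene),
estimated by RANSAC: 4-point minimal samples solved by Hartley-normalized
DLT, forward-transfer inlier threshold (default 3 px), adaptive early exit
at 99% confidence, least-squares refit on the inliers, and normalization to
$H_{33} = 1$. A point transfers as

$$S \begin{pmatrix} u' \\ v' \\ 1 \end{pmatrix} = H \begin{pmatrix} u \\ v \\ 1 \end{pmatrix},$$

dividing by the scale factor $S$. Applying $H$ to the corneal `gazePoint`
yields the gaze point in scene pixels; out-of-frame results are flagged
`clipped`, never errors.

## Pooled estimation lives in the eye-image frame

One homography per session, pooled over all calibration pairs, is the
default (a per-frame mode re-estimates $H$ from each frame's own matches).
Pooling raises a frame question that the package resolves deliberately:
when the eye rotates, the corneal reflection is nearly stationary in the
*full RGB eye image* — a spherical mirror surface does not move when the
sphere spins — while the crop tracks the moving pupil. Matches expressed in
crop-local coordinates therefore shift from frame to frame, and a single
homography fitted to pooled crop-local coordinates would mix inconsistent
frames. The pooled model is instead estimated in full eye-image
coordinates: every match carries its crop's bbox and mirror geometry and is
lifted exactly before estimation, and `gazeToScene` lifts the gaze point
through the same geometry at query time. The per-frame mode, where no
pooling occurs, stays crop-local. `HomographyModel@frame` records which
frame a model lives in.

# Evaluation

The angular error between an estimated and a true scene gaze point
backprojects both pixels through the front-camera intrinsics and takes the
angle between the unit rays (dot product clamped to $[-1, 1]$), in degrees.
Records are grouped per participant and session; mean, sample (n-1) SD and
median are reported per participant. The median is kept alongside the mean
because a single mistracked triad can dominate a mean but only nudge a
median to a neighbouring order statistic. Both overall summaries — the
unweighted mean of per-participant means and of per-participant medians —
are reported, because published headline figures for this class of system
have used both conventions; `referenceGazeTables()` ships the 12-participant
reference tables (indoor marker-tracking and outdoor object-viewing
sessions) this package's aggregation is checked against.

# The synthetic-data generator

Every stage is testable without hardware because `simulateSession` builds a
complete session with exact ground truth:

* **Rig** (`makeRig`): headset image sizes (800 x 600, 1280 x 960,
  1280 x 960); eye-camera focal lengths drawn so the whole eyeball fits the
  frame at the working distance (IR 550-750 px, RGB 900-1200 px, front
  900-1200 px); a 5-15 mm randomized baseline between the eye cameras. The
  RGB camera is verged onto the nominal eye position — at these baselines
  and distances a parallel-mounted camera would not keep the pupil in frame
  — with a small random mounting rotation on top. The front camera faces
  the world.
* **Eye**: sphere of radius 12 mm at 30-45 mm depth; pupil is a 2 mm-radius
  circle on the sphere (an anatomically typical daylight pupil; the radius
  is a scenario parameter). Gaze directions fill a cone (default half-angle
  15 degrees) around a base gaze that passes over the eye cameras toward
  the scene.
* **Observations**: boundary points and pupil centres are projected exactly
  into both eye cameras, then perturbed with Gaussian pixel noise
  (`pixelNoiseSd`) — this *is* the pupil-detection noise. Feature matches
  are sampled in the crop, mapped through the true frame homography, and
  perturbed with match noise and a configured fraction of uniform outliers.
  Frames whose pupil leaves either eye frame are skipped and logged,
  mirroring valid-triad filtering on real recordings.
* **Timestamps**: two free-running 20 fps streams with jitter, paired at
  1 fps by nearest timestamp per window (`pairNearestTimestamps`).
* **Scene and truth**: the scene is a textured plane at 0.5-1 m, so the
  corneal-to-scene map is exactly a homography and ground truth is
  well-defined. The session's true reflection homography (full RGB eye
  image to scene) is anchored to the physical plane-gaze geometry at four
  reference gaze directions: at those anchors the homography maps the
  projected pupil centre exactly to the optical-axis/plane intersection
  seen by the front camera, and the per-event true scene gaze is defined
  through this map. That makes the noiseless pipeline an exact identity
  (closed below 0.05 degrees in the test suite), so every degree of error
  in a noisy run is attributable to the injected noise.
* **Rendering** (`renderTriad`): optional images for the image-side
  operators — IR eye image (bright background, darker iris annulus, dark
  pupil at the exact projected ellipse), RGB eye image with the corneal
  patch composited as the scene warped through the true homography, then
  blurred and resolution-degraded, and the scene texture itself. Default
  corneal degradation: blur sigma 1 px, 2x resolution loss.

Everything is deterministic given the scenario seed (two runs are
byte-identical).

## What the generator does not emulate

Passing on synthetic sessions shows the geometry, the estimators and the
plumbing are right; it does not certify performance on real recordings.
Not emulated: the systematic offset between the reflection-matched point
and the true line of sight of a real convex cornea (the generator's truth
is defined through the reflection homography itself); kappa (optical vs
visual axis); eyelids, eyelashes, glints and iris texture; dark-iris
contrast loss; non-planar scenes (a fixed $H$ is only exact for one scene
depth); headset slippage within a session; rolling-shutter and exposure
effects.

# Numerical choices and degenerate inputs

* Triangulation uses the common-perpendicular midpoint; parallel rays
  (|cosine| above $1 - 10^{-9}$) are a hard error.
* Ray-sphere intersection takes the near root; negative discriminant raises
  a typed `gazeNoIntersection` condition that batch drivers convert into an
  invalid record, never a crash.
* Sphere fit: Gauss-Newton, step tolerance $10^{-12}$, 100 iterations,
  Nelder-Mead fallback; fewer than 4 usable correspondences is an
  insufficient-data error.
* Ellipse fitting is the direct conic least-squares method with the
  ellipse constraint; non-elliptical solutions are rejected.
* Pupil segmentation: two-stage Otsu (dark structures vs background, then
  pupil vs iris inside the dark class). The second split is accepted only
  when the two dark classes are separated by more than three within-class
  standard deviations; without the guard, a noisy unimodal pupil blob gets
  split in half and the detection degrades non-monotonically with noise.
  A pixel-count band ("darkest 20% of pixels") was rejected because the
  pupil can occupy far less than 20% of the frame, leaving the band
  dominated by background.
* RANSAC draws its samples under a caller-supplied seed, restoring the
  caller's RNG state afterwards; estimation is invariant to similarity
  re-normalization of the inputs (Hartley normalization inside DLT).
* Bounding boxes use exclusive upper edges, so a full-frame box keeps its
  full width after clipping; empty boxes after clipping are errors.
* The detection score multiplies pupil/surround contrast by penalties on
  interior non-uniformity and boundary raggedness; it decreases with pixel
  noise (verified statistically over 50 seeds).

# Problem sizes used by the checks

The test suite closes the noiseless loop at 20-60 calibration frames and
25-30 corneal/scene pairs per scenario; parameter-recovery checks use 200
boundary correspondences (noiseless and 0.5 px noise over 20 seeds),
mapping consistency uses 100 random eyes, and homography recovery uses 200
matches with 30% outliers over 20 seeds. The full-pipeline check and the
acceptance script run the study-scale configuration — 100 eye-frame pairs,
220 pooled corneal/scene pairs, 500 gaze events with 1 px detection noise,
1 px match noise and 20% outliers — the script averaging five session
seeds. These sizes are the package's chosen operating points and are stated
here so results are reproducible exactly.

# Known limitations

The feature matcher is a classical corner/patch pipeline: adequate for
textured planar scenes (and exercised against rendered corneal patches),
but weaker than modern learned or gradient-histogram descriptors on real
corneal imagery; the module boundary is designed for replacement. The
pupil detector is a threshold-and-fit stand-in for a trained detector,
honouring the identical output contract. Pooled homographies assume a
quasi-static relation between eye-image and scene content over a session —
true for a stable headset and roughly constant scene depth, progressively
wrong as depth varies; the per-frame mode trades noise robustness for
freedom from that assumption.
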