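---
title: "Object-centered mapping of sit-to-stand behavior: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Object-centered mapping of sit-to-stand behavior: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stsmap)
```

## The problem

Rising from a seat is one of the highest fall-risk activities of daily
living for elderly people, and how a person rises depends on the seat: a
chair with armrests constrains the sitting position and invites the hand
onto the armrest, while a wide sofa lets the person sit far from the
armrest and rise by pitching the trunk forward — a narrower base of support
and a riskier motion. To compare such behaviors recorded by depth cameras
in *different rooms*, from *different seats*, under *different camera
placements*, the trajectories must first be brought into a common frame
that is anchored to the thing the behavior is about: the seat's standing
aid (armrest or handrail).

This package implements that comparison pipeline end to end, and a
synthetic-data generator that exercises it without any recordings.

## The object-centered coordinate system

Inputs per trial are (a) two point-cloud patches of the seat in camera
coordinates — the seat surface and the backrest (chairs/sofas) or side
frame (beds) — with an annotated anchor point $P_0$ at the base of the
armrest or handrail, and (b) the trajectory of 13 body joints (shoulders,
elbows, wrists, pelvis center, left/right pelvis, knees, ankles), also in
camera coordinates, in meters.

Each patch is fit by the plane $aX + bY + cZ + d = 0$ with $c = 1$, i.e.
the least-squares solution of $[X\ Y\ 1]\,[a\ b\ d]^T = -Z$ (solved by QR
in `fit_seat_plane()`). The $c = 1$ gauge assumes the plane is not
vertical in camera coordinates — true for a seat surface seen from a
ceiling camera, and true for backrests because they recline; the fit
refuses near-vertical input (total-least-squares normal with
$|n_z| < 0.1$) rather than mis-fitting it.

The basis is then

* $e_z \propto [a, b, 1]^T$ from the seat-surface fit (up),
* $e_x' \propto [a, b, 1]^T$ from the backrest fit (front-back, not yet
  orthogonal),
* $e_y = e_z \times e_x'$ normalized (left-right),
* $e_x = e_y \times e_z$ (front-back, re-orthogonalized).

Two choices here are deliberate corrections of ambiguities in the textbook
presentation of this construction. First, the raw plane normal
$[a, b, 1]^T$ is not unit length; we normalize every basis vector before
stacking them into $R$ (rows $e_x^T, e_y^T, e_z^T$), because only an
orthonormal $R$ yields a rigid transform. Second, the homogeneous
transform is taken as the camera-to-object map
$$H = \begin{bmatrix} R & -R P_0 \\ 0 & 1 \end{bmatrix},
\qquad p_{\text{object}} = R\,(p_{\text{camera}} - P_0),$$
so the anchor maps to the origin — the form $[R\ P_0; 0\ 1]$ maps the
other way.

The $c = 1$ fit always reports a normal with positive camera-$z$, so the
axes carry a sign ambiguity. It is resolved from the data, deterministically:
$e_z$ is flipped so the trial-mean shoulder position lies on the positive
side of the seat plane (up points from seat toward shoulders), and $e_x$
is flipped — together with $e_y$, preserving right-handedness — so the
pelvis center's net first-to-last displacement has non-negative $e_x$
component (forward is the direction of standing travel). Degenerate seats
(backrest plane parallel to the seat plane) are an explicit error.

The testable content of this construction is camera-pose invariance: the
same behavior rendered under two poses, each normalized with its own
seat's frame, must agree. On noise-free synthetic data the suite requires
agreement within $10^{-6}$ m per joint per frame, and below $10^{-3}$ m
in the summed trajectory distance.

## Time normalization and dissimilarity

Behaviors have different durations, so each of the 39 coordinate channels
is interpolated by a natural cubic spline over normalized time
$u = (t-1)/(T-1)$ and evaluated at 500 equispaced points
(`resample_sequence()`). Choices: natural boundary conditions (no
curvature information at the endpoints exists), frame-index
parameterization unless the file carries timestamps (recordings at a
fixed frame rate make the two equivalent), endpoints pinned to the data,
and sequences shorter than 4 frames rejected rather than padded (a cubic
spline needs 4 knots; real trials are 60+ frames).

The dissimilarity of joint $j$ between behaviors $K$ and $L$ is the
Manhattan distance between trajectories,
$$D_j(K, L) = \sum_{t=1}^{500} \lVert J_{Kt} - J_{Lt}\rVert_1,$$
with the $L_1$ norm over the three coordinates, and
$D_{\text{sum}} = \sum_{j=1}^{13} D_j$ (meters). Taking $|\cdot|$ on a
3-vector as the $L_1$ norm is an interpretation — it is what makes the
per-joint matrix literally a Manhattan distance on the flattened
$500 \times 3$ trajectory, hence a metric; a Euclidean-per-frame variant
is available (`norm = "euclidean_per_frame"`) but is not the default.
Segmentation of the sit-to-stand within a longer recording is assumed
done upstream.

## Clustering, model selection, averages

Hierarchical clustering runs on $D_{\text{sum}}$ with average linkage
(UPGMA, the default) or Ward. Ward formally assumes squared Euclidean
input; running it on a Manhattan-sum matrix is kept as a
linkage-robustness check (it reproduces the UPGMA partition on this
data), with a logged caveat. The cluster count is chosen by the mean
silhouette coefficient $s_i = (b_i - a_i)/\max(a_i, b_i)$ (singletons
contribute 0), scanned over $k = 2, \dots, \min(12, n-1)$; ties go to the
smallest $k$ (parsimony). Each cluster is summarized by the elementwise
mean of its members' resampled trajectories
($X_{\text{ave}} = \tfrac1n \sum X_i$), its representative motion.

## The 2-D map

Metric multidimensional scaling minimizes the raw stress
$$\sigma(Z) = \sum_{i<j} \bigl(d_{ij} - \lVert z_i - z_j\rVert\bigr)^2$$
by iterative majorization (SMACOF): the Guttman transform
$Z \leftarrow \tfrac1n B(Z) Z$ decreases stress monotonically, which the
suite asserts. Eight restarts are run — one initialized from classical
scaling, seven from seeded random configurations — and the minimum-stress
run is kept. MDS is defined only up to rotation, reflection and
translation; for reproducibility the configuration is centered, rotated
onto its principal axes, and sign-fixed per axis by its largest-magnitude
coordinate. Convergence uses a relative stress-decrease tolerance of
$10^{-12}$ (up to 2000 iterations), tight enough that exactly embeddable
inputs (a 3-4-5 triangle, any planar Euclidean configuration) reach
stress below $10^{-6}$.

The map is annotated with each trial's seat type (product), Barthel Index
(physical ability, 0–100) and MMSE (cognitive ability, 0–30), producing
the three colorings used to ask whether map position follows the seat or
the person.

## What the synthetic generator emulates

`simulate_library()` reproduces the composition of the 24-trial study the
pipeline was built for: 6 participants, 5 nursing-bed, 8 chair and 11
sofa trials, with each participant's sex, BI and MMSE; trials `no31_4`
and `no32_2` carry the forward-lean archetype and the other 22 the
armrest-assisted one — the two-cluster structure reported for the
recorded data, planted in the kinematics.

Each trial renders three key poses (seated, transition, standing),
interpolated per coordinate by a natural cubic spline over normalized
time, plus isotropic Gaussian jitter (default `noise_sd = 0.01` m,
roughly depth-camera skeleton noise). The archetypes differ in where the
person sits relative to the standing aid (`anchor_gap` 0.25 m vs 0.60 m —
next to the armrest vs near the sofa center), where the hands go
(armrest base vs knees), peak trunk pitch (0.15 vs 0.60 rad) and shoulder
forward excursion (0.05 vs 0.25 m). The recorded study reports no
numeric kinematics, so these are the package's own choices, made once so
that the archetypes are cleanly separable at the default noise; a
`separation` dial scales the contrast continuously to 0 for studying the
breakdown of recovery. Trial durations are drawn uniformly from 60–150
frames (2–5 s at a depth camera's 30 fps; the study states no durations).
Seat scans are uniform samples of the two planes, moved by a random
ceiling-camera pose (yaw free, tilt ≤ 12° so both planes stay
representable under the $c = 1$ gauge), with the anchor stored noise-free
— it is an annotation, not a measurement.

What the generator does **not** emulate: pose-estimation artifacts
(occlusion, missing or swapped joints, outliers far beyond Gaussian
jitter), within-archetype kinematic idiosyncrasy between participants,
non-planar or cluttered seat scans, and segmentation errors at the trial
boundaries. Passing tests therefore show that the pipeline's geometry,
metrics and model selection are correct and that the planted structure is
recoverable under realistic noise — not that real recordings of new
participants will cluster this cleanly.

## Problem sizes and numerical tolerances used in the checks

The verification suite runs the full 24-trial pipeline across 20 seeds
(requiring the 2-vs-22 split with the correct minority members in at
least 18), checks pose invariance on 50 behavior/pose-pair triples,
compares distances, UPGMA merge sequences, silhouettes and averages
against naive brute-force oracles at $n \le 8$ (tolerance $10^{-9}$), and
asserts noiseless geometric exactness at $10^{-12}$. These sizes make the
whole suite run in well under a minute while leaving each property
nowhere to hide.

## Limitations

Real deployments need the anchor annotated per seat (no automatic armrest
detection), pre-segmented trials, and the 13-joint skeleton in the
canonical order. Dynamic-time-warping dissimilarities and non-hierarchical
clustering are out of scope here, as is any statistical test of the
cluster–covariate associations the maps visualize: the maps support
visual inspection, nothing stronger. The $c = 1$ plane gauge restricts
camera placement to broadly downward-looking views; cameras near seat
level would need a different parameterization.
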