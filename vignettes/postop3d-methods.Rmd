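---
title: "postop3d: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{postop3d: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

After an osteotomy-type intervention — the running example is the
periacetabular osteotomy (PAO), in which four pelvic cuts free the
acetabular fragment, the fragment is reoriented, and three to four screws
fix it — outcome assessment asks three quantitative questions of the pre-
and postoperative CT pair:

1. **Where were the cuts made?** Each osteotomy is summarized as a plane
   (center point and unit normal, world millimetres).
2. **How was the fragment repositioned?** A 6-DOF rigid transform
   `FpostTFpre` describing the fragment's motion between the scans.
3. **Where are the implants?** Per screw: axis direction (pointing toward
   the head), center of mass, and the entry point at the screw head.

`postop3d` computes all three fully automatically and ships a synthetic
phantom generator that provides exact ground truth for every stage, so the
whole pipeline is testable end to end without clinical data.

## Pipeline

### Cut detection and plane fitting

Cuts are located as labelled voxel regions (labels 1–4, one per osteotomy)
in the cropped postoperative CT. Two segmentation backends exist: an
*oracle* backend that returns the phantom's ground-truth labels — making
all downstream geometry testable in isolation — and a *network* backend, a
compact volumetric U-Net (five 3×3×3 convolution blocks with leaky-ReLU
activations and 2×2×2 max pooling, 16 filters doubling per block, mirrored
decoder with skip concatenation, softmax head). The multi-class network
trains with a weighted categorical cross-entropy; the default class
weights `c(10, 270, 260, 270, 260)` compensate for the extreme rarity of
cut voxels relative to background. The per-voxel loss is averaged over
voxels (a sum would only rescale the learning rate). Training uses Adam
under a piecewise-constant schedule (1e-4 for the first ten epochs, 1e-5
afterwards).

A plane is then fitted to each labelled region by PCA: center = centroid
of the voxel centers (in world mm, so anisotropic spacing does not bias
the fit), normal = eigenvector of the point covariance with the smallest
eigenvalue. The normal's sign is left unresolved at this stage.

### Fragment repositioning

Repositioning is quantified by two masked rigid registrations with a
normalized-correlation (Pearson) metric and a regular-step gradient
descent optimizer on a versor + translation parameterization:

* **Coarse stage.** Fixed image = preoperative CT, moving = postoperative
  CT, metric restricted to the preoperative pelvis mask (oracle bone mask
  or the binary pelvis network — same U-Net with a sigmoid head and the
  Dice-CE loss `0.5 * CE + 0.5 * (1 - soft Dice)`). The result `T1` maps
  preoperative into postoperative coordinates. Initialization aligns the
  bone-mask centroids (the optimizer's capture range then comfortably
  covers scan-frame offsets of ~10° / 10 mm).
* **Plane orientation.** The joint center is approximated as the mean of
  the four plane centers and each normal is flipped toward it, giving the
  inward orientation used by the fragment rule.
* **Fragment mask.** A voxel belongs to the fragment iff its signed
  distance to *every* oriented plane is strictly positive. The rule is
  applied to the postoperative bone mask (the pelvis segmentation of the
  postoperative scan, or an HU threshold with metal excluded), minus a
  `cut_margin` band (default 3 mm, half the callus thickness) around each
  plane. The support choice matters: the voxels the fragment vacated hold
  soft tissue postoperatively and the voxels it newly occupies were not
  bone preoperatively, so a preoperative mask carried over by `T1` misses
  much of the fragment; and the peri-cut band contains callus, which has
  no pre/post correspondence and measurably biases the fine optimum.
* **Fine stage.** Fixed image = postoperative CT restricted to the
  fragment mask, moving = preoperative CT. Initialization aligns the
  fragment centroids (the plane rule evaluated in both frames), and the
  optimization is a small deterministic multi-start: twenty candidate
  starts (the centroid alignment, rotations of 10 and 20 degrees about
  each axis, 6 mm translations along each axis, and plain `T1^-1`) are
  scored by the metric, the best three are optimized fully, and the best
  final metric wins. A single start stalls in translation-offset local
  optima on a noticeable fraction of phantoms; the multi-start removes
  every such failure seen in testing at about twice the fine-stage cost.
  The residual fragment motion in the postoperative frame is
  `T2 = total o T1^-1`, and `total = T2 o T1` is the full fragment map
  compared against ground truth.

Optimizer details (the published hyperparameters leave these open):
rotation center = mask centroid (required for the stated translation
scales — 1/2000 coarse, 1/500 fine — to be meaningful); gradients by
central finite differences (1e-4 versor units, 0.05 mm); the scaled
gradient is normalized, the step starts at the maximum step length and
halves whenever the gradient direction reverses, stopping at the minimum
step length or 200 iterations; the best-seen metric value is returned, so
the metric never degrades below its value at the initialization. With
full (or strided) in-mask sampling the whole procedure is deterministic.

### Screw quantification

1. **Thresholding** the postoperative CT at HU > 2500 (strict) isolates
   metal; the voxel centers form the point cloud.
2. **Iterative 3D Hough transform** for lines: directions discretized on
   one hemisphere of a level-4 subdivided icosahedron (~1.3° resolution);
   for each direction the centered points are projected onto the
   orthogonal anchor plane and voted into `dx`-wide cells. The global
   maximum seeds a line; points within `dx` are assigned; the line is
   refitted by orthogonal regression, iterated with re-assignment to a
   fixed point (this makes the result independent of the voting-grid
   alignment); assigned points are removed and the process repeats until
   `nlines` lines are found or support falls below `minvotes` (applied to
   both the raw vote count and the refined assigned count). Defaults
   `nlines = 6`, `minvotes = 50`, `dx = 3` mm. Note `minvotes` counts
   cloud points and therefore scales with voxel volume: at 1 mm voxels a
   2 mm-radius screw contributes ~750 points, at 2 mm voxels only ~90,
   where `minvotes = 20` is the equivalent setting.
3. **Entry points** by Amanatides–Woo fast voxel traversal: from the
   line's center of mass along the direction (oriented toward the screw
   head by the anatomical head axis, default superior `+z`), the ray
   visits each crossed voxel exactly once until the contiguous foreground
   run ends; the last foreground voxel center is the entry point. No
   sub-voxel refinement is attempted, so the entry error is bounded below
   by about half a voxel.

### Evaluation geometry

Landmarks P1–P5 (most superior point of the supraacetabular cut on the
bone surface, most medial points on the plane-1/2 and plane-2/3
intersection lines, most anterior ischial and most posterior pubic
surface intersections) are computed under a configurable anatomical
convention (default +x left, +y posterior, +z superior; "medial" is
toward the surface's midsagittal plane). Surface∩plane membership uses a
half-voxel-diagonal tolerance; intersection-line extrema are clipped to
the surface bounding box (an infinite line has no extremum). P1–P4 are
projected onto their least-squares plane; the connecting vectors V1–V3
give the 2D angles SR = angle(V1,V2) and RI = angle(V2,V3). Registration
error is the mean Euclidean distance between corresponding fragment
surface points under the two transforms being compared; mask agreement is
the Dice coefficient; screws are matched greedy mutual-nearest on entry
points with a 10 mm gate.

## The phantom

The generator emulates the cropped hip frame: a 128 mm field of view at
1 mm in a 128³ grid (the deep-learning steps downsample to 32³ at desk
scale). The scene is analytic, so no rendering artifacts other than the
deliberate ones exist:

* **Body**: union of three overlapping ellipsoids (a main body, an
  inferior and a superior lobe), cortical-bone intensity 700 HU on a
  50 HU soft-tissue background. The surface is rendered with a ~1.5 mm
  partial-volume transition, mimicking the CT point spread; without it
  the fixed image is artificially sharp relative to the trilinearly
  interpolated moving image and the fine registration acquires a ~0.4 mm
  interpolation bias.
* **Texture**: bone carries a smooth multi-scale sinusoidal field
  (two 8–14 mm components plus ~30 mm and ~60–110 mm components,
  amplitude 100 HU) anchored to the anatomy, standing in for
  trabecular/cortical structure. It travels with the fragment, which is
  what gives the masked correlation metric both its lock-in accuracy and
  its capture range; a single-scale texture demonstrably loses 10–20 mm
  displacements.
* **Cuts**: four planes drawn around a lateral joint center with jittered
  canonical orientations (supraacetabular, retroacetabular, ischial,
  pubic) at 13–19 mm distances; the fragment is the body region strictly
  inside all four inward half-spaces (~10–15 % of bone volume, matching
  the anatomy). Draws that fail to isolate an interior fragment are
  rejected and redrawn, with an error after 20 attempts.
* **Callus**: a 6 mm labelled shell straddling each cut restricted to the
  near-fragment face, elevated by +150 HU — visible evidence bridging the
  gap, as in scans taken ~15 weeks post-op. How callus intensity evolves
  with healing is not modelled; both parameters are configuration, not
  claims.
* **Repositioning**: the fragment moves by a uniform rotation of 5–15°
  about a random axis through its centroid plus a 3–10 mm translation;
  the whole scene additionally moves by a 2–5° / 2–5 mm scan-frame offset
  (the patient is never positioned identically twice).
* **Screws**: 2 mm-radius capsules, 40–80 mm long, heads at the superior
  bone surface, tips inside the repositioned fragment, minimum 6 mm
  inter-axis spacing (the close-screw regime), metal at 3000 HU. The
  ground-truth entry point is the head-end tip of the capsule.
* **Noise**: independent 20 HU Gaussian noise per scan.

Identical configuration and seed give bit-identical phantoms.

What the phantom does *not* model — and hence what passing tests do not
show about clinical data: real pelvic shape (the operators are
geometry-generic, but plane-fit errors on thin irregular callus will be
larger), metal artifacts and beam hardening, segmentation errors of a
real pelvis network trained on 27 cases, non-rigid soft-tissue change,
and controlled-fracture cuts that are curved rather than planar.

## Problem sizes and tolerances

The test suite and the acceptance script run at the sizes a workstation
handles in minutes: plane/mask/registration/screw recovery on ten 128³
phantoms each (registration with a deterministic 1-in-4 metric stride),
coarse-offset recovery on three, and segmenter training on twenty 64³
phantoms resampled to 32³ for 12 epochs (the full published schedule is
40 epochs at 128³; the architecture is resolution-agnostic, and held-out
per-cut Dice above 0.3 at desk scale is a sanity bar, not a clinical
claim). The published clinical error figures — 2.10 mm fragment MAE,
1.32 mm entry and 1.10° axis error — are used as generous upper bounds on
this far cleaner synthetic data; typical phantom results are several times
better (fragment MAE ~0.1–0.2 mm, entry ~0.7 mm, axis ~0.1°).

Numerical conventions worth knowing: voxel indices are 0-based and map to
voxel centers; resampling preserves the physical field of view exactly;
label volumes resample nearest-neighbour only; the fragment rule uses a
strict inequality, so a voxel center exactly on a plane belongs to no
fragment; Hough directions are stored sign-canonically on one hemisphere
and oriented toward the head axis only at the end; all angles between
plane normals or screw axes are sign-agnostic.

## Limitations

* The network backends are exercised at desk scale only; no claim is made
  that the shipped training harness reaches the published clinical Dice
  of 0.93 for pelvis segmentation.
* `minvotes` is resolution-dependent (see above); the default matches
  ~1 mm voxels.
* The fine registration inherits any gross failure of plane detection
  (the fragment mask is built from the planes); `detect_planes` flags
  per-plane failures rather than guessing.
* Entry points are voxel centers; sub-voxel entry localization would
  require a screw model and is out of scope.
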