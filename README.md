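# postop3d

Fully automatic 3D postoperative outcome evaluation for osteotomy-type
orthopaedic interventions from pre- and postoperative CT, with the
periacetabular osteotomy (PAO) as the reference intervention. A PAO frees
the acetabular fragment with four pelvic cuts, reorients it, and fixes it
with screws; `postop3d` quantifies all three surgical steps without manual
input:

* **Bone cuts** — each osteotomy is detected as a labelled voxel region in
  the postoperative CT (ground-truth oracle backend, or a compact 3D U-Net
  trained with a weighted categorical cross-entropy) and summarized as a
  plane by PCA: center = centroid of the region, normal = smallest
  eigenvector of its covariance.
* **Fragment repositioning** — a two-stage masked rigid registration
  (normalized-correlation metric, regular-step gradient descent, 6 DOF):
  a coarse whole-pelvis alignment `T1` of the two scans, then — after
  orienting the plane normals toward the approximate joint center (mean of
  the four plane centers) and isolating the fragment as the voxels with
  strictly positive signed distance to all four planes — a fine
  fragment-only alignment. The composition `T2 o T1` is the fragment's
  rigid map `FpostTFpre`.
* **Screw implants** — thresholding at HU > 2500, iterative 3D Hough line
  detection (hemisphere direction discretization on a subdivided
  icosahedron, `nlines = 6`, `minvotes = 50`, `dx = 3` mm, orthogonal
  regression refits), and entry-point tracing by Amanatides–Woo fast voxel
  traversal from each screw's center of mass toward its head.

A synthetic phantom generator (`make_phantom()`) produces pre/post CT
pairs with complete ground truth — cut planes, fragment transform, callus
labels, bone masks, screw geometry — so every stage is testable end to
end; see the methods vignette (`vignettes/postop3d-methods.Rmd`) for the
model, assumptions and design decisions.

## Worked example

```r
library(postop3d)

# simulate a postoperative case with known ground truth
ph <- make_phantom(phantom_config(seed = 42))

# 1. detect the four osteotomy planes (oracle labels here)
det <- detect_planes(ph$post, backend = "oracle", truth = ph$truth)

# 2. recover the fragment repositioning by two-stage masked registration
repo <- quantify_repositioning(
  ph$pre, ph$post, det$planes, ph$truth$pre_bone_mask,
  coarse_params = registration_params(sampling = 0.25),
  fine_params = fine_registration_params(sampling = 0.25),
  post_bone_mask = ph$truth$post_bone_mask)

# 3. quantify the screws
screws <- quantify_screws(ph$post)
```

Measuring the results against the phantom's ground truth — with
`normal_angle()` for the plane normals, `registration_errors()` for the
mean surface-point distance under the recovered versus true fragment
transform, and `screw_errors()` for entry/axis deviations — prints:

```
plane 1: normal error 0.13 deg, center offset 0.06 mm
plane 2: normal error 0.19 deg, center offset 0.05 mm
plane 3: normal error 0.29 deg, center offset 0.03 mm
plane 4: normal error 0.06 deg, center offset 0.08 mm
fragment transform recovered to 0.16 mm mean surface error
4 screws; mean entry error 0.60 mm, mean axis error 0.06 deg
```

So on this phantom the cut planes are recovered to a fraction of a degree
and millimetre, the fragment's rigid repositioning to 0.16 mm mean
surface distance, and the screws to sub-millimetre entry and
sub-tenth-degree axis accuracy. The published clinical errors for the
method (2.10 mm fragment MAE, 1.32 mm screw entry, 1.10° screw axis on
real CTs) serve as generous upper bounds for these much cleaner synthetic
conditions.

A command-line front end covering the same stages is installed at
`exec/postop3d`:

```sh
postop3d simulate --seed 7 --out case7/
postop3d detect-cuts --post case7/post.nii.gz --labels case7/cut_labels.nii.gz --out planes.json
postop3d screws --post case7/post.nii.gz --nlines 6 --minvotes 50 --dx 3 --out screws.json
postop3d run-all --seed 7 --out run7/
```

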