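---
title: "Detection and branch-relative pose estimation: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detection and branch-relative pose estimation: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guavapose)
```

## The problem and the model

A harvesting robot that knows only a fruit's position will often collide
with the branch the fruit hangs from. The remedy used here is a
*branch-relative pose*: for each fruit, the unit vector from the nearest
point of its mother branch to the fruit centre. That vector is
perpendicular to the branch by construction, so an end-effector
approaching the fruit along its negative direction passes the branch at
maximal clearance.

The pipeline assumes an *aligned* RGB-D frame — each pixel carries both
colour and depth in millimetres, with 0 marking "no measurement" — plus a
3-class segmentation (background / fruit / branch). Segmentation itself is
deliberately out of scope: trained networks do it far better than any
rule, and the package accepts any label map through `read_labels()` or a
matrix argument. The included `segment_baseline()` is a colour-dominance
rule sufficient for the synthetic renders and for smoke-testing real
frames; it makes no claim to field robustness.

Four geometric stages follow. Back-projection applies the pinhole model
pixel-by-pixel. Fruit detection clusters the fruit-class points by
region-growing at a fixed Euclidean radius and summarises each cluster by
a centre. Branch reconstruction thins the branch mask to a morphological
skeleton, lifts it to 3D, and fits straight line segments by sequential
RANSAC — straight segments, because each visible branch piece is short
enough that a line is an adequate local model, and because the pose
formula only needs a direction and a foot point. Pose estimation then
assigns each fruit the segment whose infinite line it is closest to and
computes the perpendicular unit vector.

## Parameters that matter

* **Clustering radius, 4 mm** (`cluster_params(distance_threshold = 4)`).
  The region-growing radius must exceed the lateral point spacing of the
  sensor (z/fₓ ≈ 2–3 mm at 0.8–1.1 m for a 365 px focal length) but stay
  below the surface gap between neighbouring fruits. Larger values merge
  adjacent fruits; smaller values shatter single fruits.
* **Minimum cluster size, 30 points** (`min_cluster_size`). Segmentation
  speckle and the steep rims of fruit caps otherwise surface as spurious
  one- or two-pixel "fruits". At the working distances above, a real
  fruit's visible cap carries hundreds of points, so 30 is conservative.
  This filter is a package addition: stray-pixel handling is undefined in
  the underlying procedure.
* **Line inlier threshold, 15 mm; 4000 candidates per round; acceptance
  strictly above 40 inliers** (`line_params()`). The threshold absorbs
  skeleton jitter, branch curvature and the branch radius itself; 4000
  two-point draws make the probability of missing a 40-point line
  negligible; the 40-inlier floor stops the detector explaining noise
  with ever-shorter segments. These are the published operating values;
  `pipeline_config(strict = TRUE)` pins all of them and disables the
  least-squares refinement below.
* **Sphere-fit centre** (`center_method`). The bounding-box (mean) centre
  is cheap but biased toward the camera on a single-view cap; the
  algebraic sphere fit is exact on noiseless cap samples and is the
  default. Degenerate fits (coplanar points, non-positive radius) fall
  back to the mean, recorded per fruit in the `center_method` column.
* **Matching tolerance, 30 mm** (`match_detections(tol = )`). Evaluation
  pairs detections with ground truth greedily by centre distance;
  30 mm ≈ one fruit radius. The matching rule is a package choice — the
  evaluation protocol it reproduces reports only the resulting counts.

## Numerical and convention choices

Pixels are 0-based with `u` = column, `v` = row; integer pixels
back-project at their centre; units are millimetres end to end. Depth 0 is
the sole invalid marker; non-finite or negative depths are mapped to 0 at
load time. Depth files are 16-bit single-channel TIFF (value = mm) —
a lossless integer-millimetre container with universal reader support —
and label maps are 8-bit PNG with codes {0, 1, 2}.

Cluster membership uses an exact fixed-radius search (dense distance
matrix for small clouds, grid-hashed cells of side equal to the radius
otherwise), so results are bit-identical to a brute-force all-pairs
computation; the test suite asserts this equivalence. Cluster growth
order and output order (descending size, ties by smallest member index)
are fixed so identifiers are reproducible.

Sequential line RANSAC redraws coincident two-point samples; accepted
models are refined by the principal axis of their inliers (switchable off
in strict mode, which keeps the raw two-point model); segment directions
follow a fixed sign convention (non-negative z, ties toward non-negative
y then x) so outputs are comparable across runs; extents are the min/max
inlier projections, kept for visualisation and the optional clamped
assignment while the pose formula itself uses the infinite line. The
literal stop rule "repeat until the branch cloud is empty" cannot
terminate once fewer points than the acceptance floor remain, so
detection stops when a round's best consensus does not strictly exceed
`min_inliers` — the natural reading of the acceptance condition's else
branch. Whether "larger than" is strict was also open; strict `>` is
implemented.

Mother-branch assignment follows the argmin over *infinite* lines exactly
as the formula is written. Because an infinite line can pass near a fruit
whose true branch is elsewhere (the documented false-mother failure), an
optional `clamp_to_extent` mode measures distance to the finite segment
instead; both behaviours are tested. A fruit centre within 1e-6 mm of its
branch line has no defined pose and is reported unposed rather than
guessed. Angle errors clamp the cosine into [−1, 1] before `acos`, so
rounding can never produce NaN; medians of even-length samples are the
mean of the two central values; the angle-limit frequency table uses
strict `<`, matching the "< 45°" column convention it mirrors.

## What the simulator emulates — and what it does not

`scene_spec()`/`render_scene()` build scenes of spherical fruits attached
perpendicular to finite cylindrical branches and render them by analytic
ray casting with a z-buffer. Stored depth is the z-coordinate of the hit
(the depth-image convention), noise is independent per-pixel Gaussian on
z, and hits at more than `max_incidence_deg` (default 50°) from the
surface normal return no depth. That last term models a real
time-of-flight behaviour — grazing returns are unreliable and dropped —
and it matters at this sampling density: an exactly-rendered sphere rim,
which no physical sensor observes, would otherwise detach as a
tangentially-connected ring at the 4 mm clustering radius.

The presets freeze the study conditions. `three_branch_canopy` places
three 4 mm-radius fruiting twigs at 800/880/960 mm — a robot working
distance; the 80 mm inter-branch separation exceeds every fruit offset,
so the infinite-line mother-branch assignment is unambiguous — carrying
five 30–35 mm fruits placed so no foreground branch stripe crosses a
fruit's projected disk (an occluding stripe cuts a cluster in two).
`two_touching_fruits` presses two soft ripe fruits 3 mm into each other
at 610 mm under an ideal (90°-validity) camera: the nearest visible
surface points then fall inside the clustering radius and the pair merges
into one detection, reproducing the known adjacent-fruit failure.
Geometric analysis during design showed the merge *cannot* occur for
positively separated spheres under exact sampling — every transition
between the two surfaces crosses a silhouette cliff larger than the
radius — so the pressed-contact configuration is the honest way to
realise this failure mode synthetically. `collinear_2d_depth_split`
projects two branch axes onto the same image line 200 mm apart in depth,
separating the 3D detector from any 2D one. `noisy_noon` re-renders the
canopy with σ = 32 mm noise, the depth error reported for this sensor
class in strong noon sunlight at 1 m.

What the renders do not contain: leaves and occluders, segmentation
errors (labels are exact), distance-dependent or correlated sensor noise,
lens distortion, fruit asphericity, and curved branches. Passing tests on
these scenes therefore demonstrates the geometry is implemented correctly
and is robust to moderate isotropic noise — not that the full system
survives field segmentation quality. The σ = 32 mm preset illustrates the
converse: at noon-sun noise the 4 mm clustering radius finds no coherent
fruit clusters at all, which matches the reported failure mode, and the
pipeline completes with empty results rather than crashing.

A known, quantifiable bias follows from skeleton-based reconstruction:
skeleton pixels back-project onto the branch's camera-facing surface, so
the fitted line sits roughly one branch radius in front of the true axis,
tilting each pose by about atan(radius / offset) — ≈ 3.7° for 4 mm twigs
and 60 mm fruit offsets, which is exactly the residual the end-to-end
tests observe. With thumb-thick branches this bias alone approaches 10°,
one reason field pose errors are reported in tens of degrees.

## Problem sizes in the test suite

The suite and acceptance script run everything at the sizes the methods
were designed for: full 424 × 512 renders for end-to-end scenes; 50
random point sets of up to 300 points for the clustering oracle (plus one
2,500-point cloud to exercise the grid-hashed search path); 100 random
spheres for fit exactness and 10 outlier-contaminated clouds for the
robust variant; one to four noisy 320 mm branch axes at the published
RANSAC parameters; and 20 random rotations for pose equivariance. The
whole suite completes in well under a minute of compute.

## Known limitations

Bounding-box centres are biased toward the camera on single-view caps
(documented, not corrected); branch radius is not estimated, so the
skeleton-line bias above is not compensated; the mother branch of a fruit
whose branch was never segmented cannot be recovered (such fruits are
reported unposed); and prior knowledge like "the mother branch tends to
be above the fruit" is left as a configuration hook rather than
implemented.
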