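# guavapose

Fruit detection and branch-relative 3D pose estimation from aligned RGB-D
frames, for vision systems that guide harvesting robots.

Knowing only where a fruit is does not tell a robot how to grasp it:
approaching from an arbitrary direction risks colliding with the branch the
fruit hangs from. This package implements the geometric half of that
problem. Given a depth image (millimetres, pinhole intrinsics) and a
3-class segmentation of the matching colour frame into background, fruit
and branch — from any trained model, or the built-in colour-rule baseline —
it:

1. **Back-projects** labelled depth pixels to a 3D point cloud:
   `x = z (u − Uₓ)/fₓ`, `y = z (v − U_y)/f_y`, `z = I_depth(u, v)`.
2. **Detects individual fruits** by Euclidean clustering of the fruit
   points (region growing with a 4 mm radius, exact neighbour search) and
   estimates each centre `cᵢ` by the cluster mean or an algebraic
   least-squares sphere fit. A RANSAC sphere fit is provided for
   outlier-contaminated reference measurements.
3. **Reconstructs branches** by thinning the branch mask to a
   morphological skeleton, S = ∪ₖ (A ⊖ kB) − (A ⊖ kB) ∘ B, back-projecting
   it, and detecting multiple 3D line segments `(pₖ, tₖ)` by sequential
   RANSAC (two-point candidates, 15 mm inlier threshold, 4000 draws per
   round, acceptance strictly above 40 inliers).
4. **Estimates each fruit's pose**: the mother branch is the segment
   minimising the perpendicular distance
   `j = argminₖ ‖(cᵢ − pₖ) − ((cᵢ − pₖ)ᵀtₖ)tₖ‖`, the nearest branch point
   is `nᵢ = pⱼ + ((cᵢ − pⱼ)ᵀtⱼ)tⱼ`, and the pose is the unit vector
   `q̃ᵢ = (cᵢ − nᵢ)/‖cᵢ − nᵢ‖` — perpendicular to the branch by
   construction, so approaching along −q̃ᵢ avoids it.

Evaluation utilities cover per-class segmentation accuracy and IOU from
confusion matrices, detection precision/recall with one-to-one centre
matching, and robust pose-error summaries
(MEDE = median θᵢ, MAD = median |θᵢ − MEDE|, plus angle-limit frequency
tables, with θ in degrees).

Because no public RGB-D orchard dataset accompanies the method, the
package ships a ray-casting scene simulator (spherical fruits attached
perpendicular to cylindrical branches, Gaussian depth noise, grazing-angle
dropout) whose ground-truth centres, branch axes and poses are known by
construction — every pipeline stage is testable against it.

## Worked example

```r
library(guavapose)

scene  <- scene_preset("three_branch_canopy", seed = 7)   # ground-truthed render
result <- run_pipeline(scene$depth, scene$labels, pipeline_config(seed = 7))
result
#> <guava_pipeline> 2736 labelled points -> 5 fruits, 3 branch segments, 5 poses (0 unposed)

tidy(result)[, c("fruit_id", "cx", "cy", "cz", "branch", "qx", "qy", "qz")]
#> # A tibble: 5 x 8
#>   fruit_id     cx    cy    cz branch     qx    qy      qz
#>      <int>  <dbl> <dbl> <dbl>  <int>  <dbl> <dbl>   <dbl>
#> 1        1 -100.  -21.0  800.      1  0     0.998  0.0652
#> 2        2   80.0 -19.0  800.      1  0     0.998  0.0631
#> 3        3  -49.4  90.1  880.      3  0.242 0.968  0.0675
#> 4        4 -172.  141.   950.      2 -0.889 0.444 -0.110
#> 5        5   96.1  53.7  880       3  0.242 0.968  0.0677
```

Each row is one detected fruit: centre `(cx, cy, cz)` in mm, the index of
its mother branch segment, and the unit approach pose `(qx, qy, qz)`. All
five synthetic fruits are found (centres exact to < 0.01 mm here, since
the render is noiseless) and every pose is perpendicular to its assigned
branch axis.

Scoring the poses against the scene's ground truth:

```r
truth <- dplyr::rename(scene$truth_fruits, x = "cx", y = "cy", z = "cz")
m     <- match_detections(result$detections, truth)
errs  <- sapply(seq_len(nrow(m$matching)), function(k) {
  p  <- tidy(result)[m$matching$pred[k], ]
  tr <- scene$truth_fruits[m$matching$truth[k], ]
  pose_error(c(p$qx, p$qy, p$qz), c(tr$qx, tr$qy, tr$qz))
})
pose_stats(errs)
#> <pose_stats> n=5  MEDE=3.74 deg  MAD=0.12 deg
#>   < 45 deg: 100.00%
#>   < 35 deg: 100.00%
#>   < 25 deg: 100.00%
```

The ~3.7° residual is the expected geometric bias of skeleton-based
branch reconstruction: the skeleton lies on the branch's camera-facing
surface, one branch radius in front of the true axis (see the methods
vignette). `autoplot(result)` draws the point cloud, fitted segments and
pose arrows in the image plane; `fruit_detection`, `branch` and pose
stages are also callable individually (`detect_fruits()`,
`reconstruct_branches()`, `estimate_all_poses()`), and
`inst/cli/fruitpose` exposes the same steps as a command-line tool.

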