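# ovicloud

Non-contact body measurement of sheep from multi-view depth-camera point
clouds.

Manual measurement of livestock body dimensions is slow, error-prone and
stressful for the animal. `ovicloud` implements the alternative: three
depth cameras (Kinect-v2-like) capture a sheep standing in a restraining
pen from the top, the side and the front; the package turns those captures
into a single reconstructed cloud and reads body dimensions off it.

The processing chain is the standard point-cloud morphometry stack, each
stage exposed as a plain R function:

| stage | functions |
|---|---|
| I/O and geometry | `read_cloud()`, `write_cloud()` (ASCII PLY/PCD/XYZ), `depth_to_cloud()`, `transform_cloud()` |
| denoising | `passthrough()`, `statistical_outlier_removal()` (μ + Rσ rule, R = 0.6), `ransac_plane()` / `remove_ground()` (550 iterations, α = 0.02 m) |
| downsampling | `conditional_voxel_filter()` — voxel-centroid thinning (`L = ⌈l_x/λ⌉`, centroid `c = (1/n) Σ P_i`) applied only where the local density condition holds |
| hole repair | `detect_holes()`, `fill_hole()` — natural cubic splines `S_i(x) = a_i + b_i(x−x_i) + c_i(x−x_i)² + d_i(x−x_i)³` interpolated across occlusion shadows |
| registration | `match_features()`, `ransac_coarse()` (three-pair sampling + SVD solve, error K vs threshold V), `kabsch()`, `icp()` (objective `f(R,T) = (1/n) Σ ‖q_i − (R p_i + T)‖²`) |
| measurement | `pca_normalize()`, `normalize_upright()`, `body_length()` (percentile trunk extent), `evaluate_accuracy()` (`error = 100·|tape − cloud| / cloud`) |
| orchestration | `pipeline_config()`, `run_pipeline()`, plus a thin CLI at `inst/cli/ovicloud` |

Since depth recordings of the original rig are not publicly deposited, the
package ships a first-class synthetic scene generator (`make_scene()`):
a procedural sheep (blunt superellipsoid trunk, leg cylinders, head) on a
pen floor, rendered into three camera views with sensor noise, flying-pixel
clutter, stray outliers, railing occlusion and a realistic
camera-calibration error — with exact ground truth for every label, pose
and dimension. All validation runs against that ground truth.

## A worked example

```r
library(ovicloud)
report <- run_pipeline(pipeline_config(list(seed = 7)))
report
#> <pipeline_report> seed 7
#>   top    raw=9898 passthrough=9764 sor=9646 ground_removed=1582 downsample=1153 repair=1153
#>   side   raw=10083 passthrough=9947 sor=9832 ground_removed=1898 downsample=1434 repair=1434
#>   front  raw=5815 passthrough=5667 sor=5565 ground_removed=1588 downsample=1218 repair=1495
#>   merged: 4082 points
#>   body length: 68.05 cm (truth 68.00 cm, error 0.07%)
```

Reading the report: each camera view starts with ~6–10k raw points; the
passthrough crop, statistical outlier filter and RANSAC ground removal
strip pen, noise and floor down to the animal (~1.6k points per view);
conditional voxel downsampling thins the dense flanks by about a quarter;
the front view gains 277 interpolated points where the railing shadowed
the chest; registration merges the three views, and the percentile trunk
extent of the pose-normalized cloud is the body length — here within
0.05 cm of the generator's exact trunk length.

Evaluating measurements against tape values uses the bundled reference
table of twenty sheep:

```r
res <- evaluate_accuracy(sheep_length_reference())
res$mean_display
#> [1] 0.79
```

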