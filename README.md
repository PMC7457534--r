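# phenomesh

Mesh-based 3D plant phenotyping for turntable multi-camera photogrammetry.

## The problem

Close-range structure-from-motion (SfM) rigs for plant phenotyping — a
rotary table plus a vertical arc of cameras — reconstruct a triangle mesh of
the plant from hundreds of overlapping photographs. Two practical questions
decide whether the traits read off such a mesh can be trusted:

1. **Which camera angles are worth using?** A camera looking straight down
   the rotation axis never changes its viewpoint relative to the plant, so
   depth is unconstrained; a camera near the horizon sees a planophile leaf
   edge-on and produces no matchable texture. Somewhere in between lies an
   optimum band of viewing zenith angles (VZA).
2. **How should per-angle reconstructions be combined?** Either build one
   partial model per camera and merge the point clouds (*Method 1*), or pool
   all images from all useful cameras into one joint reconstruction
   (*Method 2*).

`phenomesh` provides the full analysis chain for these questions, plus a
synthetic plant generator and an acquisition simulator so the chain can be
exercised — and its statistics validated — on scenes whose ground truth is
known exactly.

## The core statistics

For a reconstructed organ with directly measured area `A_m` and an
inclination threshold `T` (default 45°), every detected mesh face is scored
by its **mesh inclination angle** — the zenith angle of its normal, folded
into [0°, 90°]. The model is then partitioned into

* **stable** regions: detected faces with inclination ≤ `T`,
* **unstable** regions: detected faces with inclination > `T`,
* **undetected** regions: the area deficit `max(0, A_m − A_detected)`,

with fractions taken over `A_detected + undetected` so the three parts sum
to 1. A camera qualifies as *optimum* when its model is ≥ 95% stable, ≤ 2.5%
unstable and ≤ 2% undetected (all configurable).

Trait accuracy is reported with two error statistics:

```
error percentage              = |estimated − measured| / measured × 100%
error percentage over height  = |estimated − measured| / plant height × 100%
```

together with the absolute degree error for leaf inclination angles.

## Worked example

```r
library(phenomesh)

# a six-leaf broadleaf plant with exactly known traits
plant <- generate_plant(plant_spec())
rig   <- camera_rig(center = c(0, 0, plant$ground_truth$plant_height / 2))
sch   <- turntable_schedule()     # 41 frames, 9 degrees per step
noise <- noise_model(seed = 1)    # parallax noise + 9-consecutive-frame rule

# one partial reconstruction per camera C2..C6, then both fusion strategies
cmp <- compare_methods(plant$mesh, plant$ground_truth, rig, 2:6, sch, noise)
print(cmp)
#> method_comparison: 2610 faces (M1) vs 2601 faces (M2); NG entries M1: 0 M2: 0

head(as.data.frame(cmp)[, 1:5], 3)
#>   organ  trait   direct m1_estimate m1_error_pct
#> 1    L1   area 13.07655    13.07533            0
#> 2    L1 length 49.10000    49.10499            0
#> 3    L1  width 34.30000    34.28964            0
```

`M1` merges the five per-VZA partial models (union of detected faces,
inverse-variance fusion of vertex positions); `M2` emulates the joint
reconstruction, which only keeps faces co-visible from at least two cameras
— its detected set is always a subset of Method 1's. The error columns
compare each extracted trait (leaf area in cm², lengths in mm) against the
generator's ground truth.

The single-leaf VZA sweep behind the optimum-angle selection:

```r
res <- run_analysis(run_config(list(seed = 1)))
res$optimum$cameras
#> [1] "C2" "C3" "C4" "C5" "C6"
res$optimum$vza_range
#> [1] 12 60
```

A flat horizontal leaf is reconstructed stably from 12°–60° cameras, while
the nadir camera fails on depth (stable fraction ~1%) and cameras at ≥ 72°
fail on detection.

## Package layout

| Area | Functions |
|---|---|
| Mesh core & I/O | `triangle_mesh`, `read_mesh`, `write_mesh`, `face_areas`, `face_inclinations`, `rigid_transform` |
| Synthetic plants | `plant_spec`, `generate_leaf`, `generate_plant`, `write_ground_truth` |
| Acquisition simulation | `camera_rig`, `turntable_schedule`, `noise_model`, `visibility_runs`, `reconstruct_single_vza`, `overlap_map` |
| Region segmentation | `cumulative_area_curve`, `determine_threshold`, `classify_regions`, `select_optimum_vzas` |
| Trait extraction | `leaf_area`, `detect_tip_base`, `leaf_length`, `leaf_width`, `leaf_inclination`, `plant_height`, `stem_internode_traits`, `extract_traits` |
| Fusion & comparison | `merge_method1`, `joint_model_method2`, `completeness`, `compare_methods` |
| Error reporting | `error_percentage`, `error_over_plant_height`, `inclination_error`, `build_error_table` |
| Pipeline | `run_config`, `run_simulation`, `run_analysis` (thin CLI in `inst/scripts/phenomesh.R`) |

See `vignettes/phenomesh-methods.Rmd` for the model assumptions, parameter
choices and known limitations.
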