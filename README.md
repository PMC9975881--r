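# adosmotion

Movement-feature analysis of children's activity level from multi-person 2D
pose streams recorded during ADOS (Autism Diagnostic Observation Schedule)
assessments.

Clinicians rate a child's activity level 0/1/2 by whether the child can sit
or stand appropriately during the assessment's play activities. Session
videos are recorded routinely, and pose estimators such as OpenPose recover
per-frame skeletons of everyone in view. `adosmotion` is for researchers who
want an objective counterpart to that rating: it ingests BODY_25 keypoint
streams, picks out the participating child among the detected people,
computes movement features per activity, and correlates them with the
clinician scores.

## The method

For a keypoint at pixel position (x\_n, y\_n) and the origin point A (the
centre of the table edge next to the child's seat), the two per-frame motion
quantities are the **pixel distance** and the **instantaneous pixel
velocity**:

    L_n  = sqrt((x_n - A_x)^2 + (y_n - A_y)^2)
    dL_n = sqrt((x_{n+1} - x_n)^2 + (y_{n+1} - y_n)^2)

Four **movement features** summarise each (child, activity, keypoint):
`L_mean`, `L_std` (mean/SD of pixel distance) and `dL_mean`, `dL_std`
(mean/SD of velocity), for the neck, right wrist and mid hip across the
assessment's activities, including the composite "Table-play" of the five
table-based tasks. The statistical layer computes Pearson redundancy blocks
across keypoints (with neck-only pruning of redundant blocks), Spearman
correlations of each feature with the activity-level scores
(Benjamini–Hochberg corrected within each activity), and a correlation
power analysis by the bias-corrected Fisher-z method.

A child-selection filter resolves the multi-person streams: nearest-neighbour
gating on the neck keypoint with a confidence floor, a gate radius, and
re-initialisation at the child's seat after long gaps; selection quality is
audited as a mismatch rate against ground truth or a manual audit table.

Because no public keypoint data exist for this setting, the package includes
a first-class synthetic cohort generator: a mean-reverting random walk with
score-dependent excursion and step scales, per-keypoint detection noise and
missingness, burst-present distractor skeletons, and the canonical activity
timeline — enough structure to exercise every pipeline stage end to end.

## Worked example

```r
library(adosmotion)
demo_pipeline(seed = 7, n_children = 12)
```

```
<correlation_report> 12 children

Spearman correlation with activity-level scores (BH-corrected per activity):
       activity keypoint feature   rho    p_raw     p_bh  n
   Balloon-play        1  L_mean 0.916 2.85e-05 5.69e-05 12
   Balloon-play        4  L_mean 0.916 2.85e-05 5.69e-05 12
     Table-play        1   L_std 0.916 2.85e-05 4.88e-05 12
     Table-play        4 dL_mean 0.916 2.85e-05 4.88e-05 12
 ...

Power analysis: n = 12, r = 0.5, alpha = 0.0125 -> power = 0.199

Retained after redundancy pruning (Table-play): L_mean@kp1, L_std@kp1,
dL_mean@kp1, dL_mean@kp4, dL_mean@kp8, dL_std@kp1, dL_std@kp4, dL_std@kp8
```

The table ranks features by their Spearman correlation with the clinician
scores: in this 12-child demo cohort, position-based features and the mean
velocity track the score closely (rho ≈ 0.92). The pruning line shows the
redundancy logic at work: the position features are interchangeable across
keypoints, so only the neck variants are kept, while the velocity features
stay keypoint-specific. The power line reports that 12 children would be far
too few to reliably detect a true correlation of 0.5 at the planned
per-comparison level (0.05/4 = 0.0125); at the full cohort size the same
analysis gives

```r
correlation_power(n = 52, r = 0.50, alpha = 0.0125)
#> [1] 0.9144096
```

At full size (`demo_pipeline(seed = 1, n_children = 52)` or
`run_pipeline(pipeline_config(seed = 1))`) the default cohort yields
Table-play SCC(L_mean, neck) ≈ 0.85, a mean audited mismatch rate below 1 %,
and PD redundancy blocks above 0.95.

A shell entry point with `demo`, `simulate` and `run` subcommands is
installed at `inst/cli/adosmotion.R`:

```sh
Rscript inst/cli/adosmotion.R simulate --out cohort_dir --seed 3
Rscript inst/cli/adosmotion.R run --input cohort_dir --out results_dir
```

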