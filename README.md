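# contourdose

Geometric agreement metrics are the standard currency for judging
auto-segmented organs-at-risk (OARs) in radiotherapy, but they say nothing
about what actually matters clinically: whether the dose statistics a planner
reads off a contour would change had the contour been drawn differently.
`contourdose` implements, as a tested and reusable R pipeline, the analysis
that relates the two for head-and-neck plans: it compares auto-contours
against their clinically edited versions geometrically, transposes the
planned dose over both versions, flags pairs whose clinical-objective dose
differs by at least a configurable threshold (200 cGy by default — about 3%,
or one fraction, of a typical 69.96 Gy prescription), and stratifies the
flagged pairs by their distance to the closest planning target volume (PTV).
A synthetic phantom-cohort generator makes every stage testable end to end
without patient data.

It is intended for medical-physics and auto-segmentation QA work: evaluating
contour-QA thresholds, prototyping review triage rules, and teaching why
high Dice near a target is not a safety guarantee.

## What it computes

For each auto/clinical contour pair (binary masks on one voxel grid):

- **DSC** — volumetric Dice, `2|A∩B| / (|A|+|B|)`.
- **sDSC(τ)** — surface Dice at tolerance τ (default 2 mm): the
  area-weighted fraction of the two voxelized surfaces lying within τ of
  each other. Surfaces are exposed-face surfels (face centers weighted by
  face area in mm²), so anisotropic spacing is handled exactly.
- **HD** — the maximum Hausdorff distance between the two surfaces
  (the true 100th-percentile variant, which preserves the large tails that
  clinical cropping of tubular organs produces).
- **D0.01cc** ("D_max") — the maximum dose received by at least 0.01 cc of
  the structure, by whole-voxel accumulation; **D_mean** — the
  volume-weighted mean dose. Both are evaluated for *both* contours under
  the same dose grid, and differenced (signed, auto − clinical, with
  absolute values used in all summaries).
- **ΔD_CO** — the absolute difference in the organ's clinical-objective
  metric: D0.01cc for most head-and-neck OARs, D_mean for larynx,
  submandibular glands and parotids.
- **Distance to the closest PTV** — minimum Euclidean surface-to-surface
  distance in mm, 0 when the OAR overlaps a PTV.

Cohort level: per-organ summary tables (mean/SD of the geometric indices,
median and 90% quantile of the absolute dose differences, flagged counts and
ranges), pooled coverage percentiles, two-sided Wilcoxon signed-rank tests
on the signed differences (Pratt zero handling, exact enumeration for small
nonzero counts), per-organ and pooled R² of each geometric metric against
each absolute dose difference, flag-proportion curves over binned DSC / sDSC
/ HD, proximity stratification of flagged pairs at a 2.5 cm cutoff, and
sensitivity scenarios (≥ 40 Gy inclusion filter; 3% and 5%
prescription-relative thresholds).

Volumes are NIfTI (axis-aligned affines only); cohorts are described by a
JSON manifest; results are CSV + JSON.

## Worked example

Two illustrative fixtures show why geometric and dosimetric agreement
decouple near a target:

```r
library(contourdose)
fx <- make_scenario_cases()           # 2 mm voxels, 12 mm PTV, 6996 cGy
a <- evaluate_fixture(fx$A)           # large organ, tiny protrusion into the gradient
b <- evaluate_fixture(fx$B)           # small far organ, substantially shrunk
cols <- c("organ", "dsc", "sdsc", "hd_mm", "abs_delta_dmax_cgy",
          "distance_to_ptv_mm", "flagged")
print(rbind(a, b)[, cols], digits = 3)
#>       organ   dsc  sdsc hd_mm abs_delta_dmax_cgy distance_to_ptv_mm flagged
#> 1     brain 0.997 0.989  3.46             1899.6                  2    TRUE
#> 2 cochlea_l 0.350 0.778  2.45               34.6                 18   FALSE
```

Fixture A has near-perfect geometry (DSC 0.997) yet a 1900 cGy difference in
D0.01cc, because its 9-voxel protrusion reaches into the steep dose gradient
2 mm from the PTV — it flags. Fixture B has poor geometry (DSC 0.35) but
sits ~2 cm away in the flat dose far-field, so its D0.01cc moves by only
35 cGy — it does not flag.

A full phantom cohort (12 organ templates in three PTV-distance classes,
57% of auto-contours used as-is, exponential dose fall-off with λ = 5 mm):

```r
gen <- generate_cohort(sim_config(seed = 1), "cohort/")
results <- run_cohort(gen$manifest_path, analysis_config())
print(results)
#> <cohort_results> 216 records (0 unevaluable)
#> <cohort_summary> 216 pairs (60% identical), 26 flagged (12.0%)
#>   coverage: DSC p10 0.451 | sDSC p10 0.381 | HD p90 4.55 mm
#>   |dDmax| < thr: 80.6% | |dDmean| < thr: 96.3% | Wilcoxon p: 0.351 / 0.218
#>   organs tabulated: 12
write_cohort_results(results, "results/")   # records.csv, summary.json, curve_*.csv
```

All 26 flagged pairs lie within 2.5 cm of the PTV; none of the organs placed
beyond 5 cm ever flags, and the flagged proportion falls with increasing DSC
bin — the behavior the flagging rule is designed to exploit.

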