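---
title: "Relating geometric and dosimetric agreement in contour QA: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relating geometric and dosimetric agreement in contour QA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(contourdose)
```

This vignette is the package's own account of its methods: what is computed,
under which conventions, what the synthetic phantom emulates, and where the
design was genuinely open.

## The problem

Auto-segmentation systems propose organ-at-risk (OAR) contours that
clinicians edit (or accept as-is) before planning. Geometric agreement
indices — Dice, surface Dice, Hausdorff distance — are cheap to compute and
widely reported, but plan safety is judged on dose statistics, and the two
can disagree in both directions: a geometrically excellent contour abutting
the target can hide a clinically meaningful dose difference, while a
geometrically poor contour in the low-dose periphery is dosimetrically
irrelevant. The pipeline quantifies this relationship pair by pair: one
planned dose distribution is transposed over both the unedited auto-contour
and the clinical contour, the dose statistics are differenced, pairs whose
clinical-objective difference reaches a threshold are flagged, and the
flagged set is examined against PTV proximity and against binned geometric
agreement.

## Data model and coordinate conventions

All volumes live on an axis-aligned voxel lattice (`image_grid`): dims,
spacing in mm, and the world position of the center of voxel (0,0,0).
Voxel indices are 0-based in world arithmetic; the center of voxel
(i,j,k) is at `origin + (i,j,k) * spacing`, and *all* distances are measured
in world mm, so anisotropic spacing is handled uniformly. NIfTI files whose
affine contains a rotation or a flip are rejected rather than resampled:
resampling a binary mask would itself perturb the metrics under study. For
the same reason the two masks of a pair must share a grid, and only the dose
is resampled (trilinearly, once per contour lattice per patient; target
voxels outside the dose extent receive 0 cGy with a logged count). Dose is
in cGy everywhere, matching how the flagging threshold is stated.

## Geometric metrics

Surfaces are discretized as **exposed-face surfels**: each face of an
occupied voxel whose 6-neighbor is unoccupied (or outside the grid, so
scan-edge-truncated structures still close) contributes a point at the face
center weighted by the face area in mm². This representation was chosen over
boundary-voxel centers or marching-cubes meshes because it gives exact area
weights for surface Dice, well-defined surface-to-surface distances under
anisotropic spacing, and a brute-force oracle cheap enough to test against
exhaustively; no particular surface discretization is claimed to match any
other implementation.

- DSC is voxel-count Dice.
- sDSC(τ) = (area of each surface within τ of the other) / (total area),
  with point-to-surface distance the minimum Euclidean distance to the other
  set's surfel centers. τ defaults to 2 mm, the conventional center value
  for contour QA.
- HD is the maximum over both directions of the largest nearest-surfel
  distance — the true maximum, not HD95, because clinical cropping of
  tubular organs (cord, esophagus, larynx) produces exactly the >40 mm tails
  a percentile variant would erase.

Bit-identical pairs short-circuit to (1, 1, 0) and are marked `identical`,
making the used-as-is fraction of a cohort directly observable. The distance
kernel is a small C++ brute-force scan; tests require it to match an
independent all-pairs R implementation to 1e-9 mm on random masks.

One analytic subtlety: for two isolated voxels with centers 10 mm apart, HD
is 10 mm (each voxel's *far* face is 10 mm from the other's near face),
while the OAR-to-PTV distance — a min-min, not a max-min — is 9 mm. The
tests pin both.

## Dose metrics

D0.01cc is computed by whole-voxel accumulation: in-structure voxel doses
are sorted descending (ties broken by ascending linear index, so the
statistic is deterministic) and voxel volumes accumulated until 0.01 cc is
reached; the dose of the last voxel included is returned. No sub-voxel or
DVH interpolation is applied — whole-voxel accumulation is reproducible and
oracle-checkable, and nothing in the problem fixes a finer convention.
Structures smaller than 0.01 cc (lenses on coarse grids, small synthetic
organs) fall back to their minimum dose with a warning instead of erroring.
A 1e-9 cc slack guards the accumulation against floating-point rounding at
exact multiples of the voxel volume.

Deltas are signed auto − clinical; every summary uses absolute values, which
sidesteps any sign-convention ambiguity, while the signed values feed the
Wilcoxon test. ΔD_CO is |ΔD0.01cc| for organs constrained by near-maximum
dose and |ΔD_mean| for larynx, submandibular glands and parotids.

## Proximity

OAR-to-PTV distance is the minimum surface-to-surface distance, clamped to 0
on voxel-wise overlap. A surface definition (rather than centroids) is used
because "within 2.5 cm" must include organs abutting or inside the target,
which centroid distance misrepresents. The cutoff comparison is inclusive
(≤), fixing otherwise-ambiguous boundary behavior; 25 mm is the review
cutoff and 30 mm the tabulation cutoff.

## Statistics

- **Flagging**: ΔD_CO ≥ threshold (inclusive), 200 cGy by default; in
  relative mode the threshold is 3% or 5% of each patient's prescription.
- **Quantiles**: linear interpolation between order statistics (R type 7),
  stated once and used everywhere; dose quantiles are always on absolute
  deltas.
- **Wilcoxon signed-rank**: two-sided, with Pratt zero handling — zeros are
  midranked together with the nonzero differences and then dropped from the
  rank sum. Classic zero-dropping would discard the large point mass of
  bit-identical pairs (more than half of a realistic cohort) and overstate
  significance. With ≤ 15 nonzero differences the null distribution of the
  positive-rank sum is enumerated exactly by convolution (two-sided p =
  `min(1, 2·min(lower tail, upper tail))`, verified in tests against full
  sign-assignment enumeration); beyond that, a normal approximation with
  Pratt zero correction and tie correction is used. All-zero input returns
  p = 1 with a note.
- **R²**: squared Pearson correlation (equal to OLS R² of the absolute delta
  on the metric); constant response or predictor is defined as R² = 0 so
  all-identical strata summarize cleanly; fewer than 3 points gives NA.
- **Binned curves**: DSC/sDSC in half-open 0.1-wide bins with the top bin
  closed at 1.0 (perfect agreement belongs in the best bin); HD in 2 mm
  bins. Empty bins are kept with NA fractions so curves align across runs.
- Records unevaluable for dose (an empty mask in the pair) are excluded from
  every denominator but counted and logged.

## The synthetic phantom

Because paired clinical contour sets with dose are not publicly
distributable, the generator builds phantom cohorts that reproduce the
*structure* of the problem:

- **Grid**: 64³ voxels of 2 mm (128 mm cube) — coarse enough to run hundreds
  of pairs in seconds, fine enough that a 0.18 cc lens spans ~20 voxels.
- **PTV and dose**: a 12 mm spherical PTV prescribed 6996 cGy; outside it
  the dose decays as `Rx · exp(−d/λ)` with d the distance to the PTV surface,
  clamped at a 30 cGy floor. λ = 5 mm gives the steep clinical gradient
  regime; the exponential is the simplest monotone model with one steepness
  knob. Optional Gaussian noise is off by default.
- **Organs**: twelve templates spanning lens-scale (~0.2 cc) to brain-scale
  (~45 cc), placed in three distance classes — overlapping/abutting the PTV,
  within 25 mm, and beyond 50 mm. The near class deliberately contains small
  structures (cochlea, submandibular gland, optic nerve, spinal cord) as in
  head-and-neck anatomy: sizeable contouring errors on small near-target
  structures are what produce low DSC *and* large dose differences
  simultaneously, the regime that makes the flag-proportion-vs-DSC curve
  fall. The far class (orbital structures) sits in the exactly-flat floor
  region, so its dose deltas are identically zero regardless of
  perturbation.
- **Perturbations**: each auto-contour is the clinical template with one
  seeded perturbation — identity (probability 0.57, matching the typical
  used-as-is fraction), dilation or erosion (face-connected morphology),
  whole-voxel translation nearest to a 2–8 mm draw, truncation of distal
  axial slices (the clinical-cropping error), or deletion of interior slices
  (the forgotten-interpolation error). A draw that would empty a small
  structure is downgraded to a 1-step dilation and recorded as such in the
  ground truth. Templates are deterministic: changing the seed changes only
  the perturbation draws.
- **Defaults**: 18 patients × 12 organs = 216 pairs — large enough for
  stable bin curves, small enough that generation plus the full pipeline
  runs in about a minute on one core.

What passing tests on this phantom do **not** show: realistic VMAT dose
(multiple dose levels, heterogeneity corrections), inter-patient anatomical
variation, observer-style contour edits (the perturbations are clean
morphological operations), or DICOM ingestion. The phantom validates the
pipeline's arithmetic and its qualitative regime — steep-gradient flagging,
proximity concentration, trend recovery — not cohort-level clinical numbers,
which depend on unavailable patient data.

Two hand-built fixtures pin the decoupling cases: fixture A (large organ
whose auto version adds a 9-voxel protrusion into the gradient 2 mm from
the PTV) must flag despite DSC > 0.95; fixture B (small organ ~2 cm away,
eroded to a third of its volume) must not flag despite DSC < 0.7.

## Degenerate inputs and numerical choices

- Both masks empty: geometric comparison errors (undefined); one mask empty:
  the pair becomes an unevaluable record with a reason.
- Empty mask surfaces are empty surfel sets; grid-boundary faces count as
  exposed.
- Interpolated dose is clamped at 0 against sub-1e-9 negative round-off.
- DSC/sDSC bin edges are rounded to 12 decimals so bins land on exact
  decimal boundaries.
- The records CSV serializes numeric fields at full precision (`%.17g`), so
  pipeline runs are byte-reproducible and read-back is exact.

## Known limitations

- NIfTI only; no DICOM RTSTRUCT/RTDOSE ingestion, by design.
- HD and sDSC are volumetric and surfel-based; values are not claimed to
  reproduce mesh-based or slice-wise implementations.
- Patient clustering is ignored in the pooled tests (no mixed-effects
  modeling), and no multiple-testing correction is applied — the pooled
  Wilcoxon tests are reported singly.
- The relative-threshold mode requires per-patient prescriptions in the
  manifest and applies one prescription per patient (no per-dose-level
  thresholds).
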