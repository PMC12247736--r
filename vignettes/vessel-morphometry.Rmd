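---
title: "Vessel morphometry from binary masks: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vessel morphometry from binary masks: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselmorph)
```

`vesselmorph` turns a binary cerebrovascular mask into a per-subject vector
of morphological features and provides the statistical protocol for relating
those features to phenotypes. This vignette documents the model behind each
stage, the conventions and tunable parameters, what the synthetic phantoms do
and do not emulate, and the package's known limitations.

## The measurement model

A segmentation is a binary field on a voxel lattice tied to physical space by
the NIfTI affine. All reported quantities are physical: lengths and radii in
mm, volumes in mm³. Voxel indices are never reported as measurements; the
affine (and hence anisotropic spacing such as 0.47 × 0.47 × 0.8 mm) enters
every computation.

The pipeline is:

mask → thinning → centerline classification → distance-transform radii →
segment decomposition → per-segment geometry → feature aggregation.

### Thinning

The centerline is produced by 6-subiteration medial-axis thinning: in each
pass, border voxels of each of the six face directions are deleted when they
are *simple points* — voxels whose removal changes neither the number of
26-connected foreground components nor the number of 6-connected background
components of their 3×3×3 neighborhood (the Bertrand–Malandain
characterization) — and are not curve endpoints (voxels with a single
foreground neighbor). Candidates found in a parallel scan are re-checked
sequentially before deletion, and passes repeat until a fixed point. The
result is idempotent, a subset of the mask, and preserves component counts;
these contracts are tested property-style on randomized masks.

One behavior of this algorithm family is worth knowing: a structure that is
*exactly* symmetric about a plane between voxel centers (e.g. a cylinder
whose axis lies precisely halfway between lattice columns) has no privileged
center voxel, and thinning can collapse it almost entirely; the reference
implementations in common image-analysis libraries behave the same way. Such
exact lattice commensurability is measure-zero in real data. The phantom
generator deliberately offsets all curves by a generic sub-voxel amount so
that its outputs are representative rather than adversarial.

### Topological classification and junction nodes

Each centerline voxel is classed by its count of centerline neighbors in the
26-neighborhood: 1 → endpoint, 2 → regular, ≥3 → bifurcation (0, an isolated
voxel, is an endpoint). 26-connectivity is the standard convention for 3D
curve skeletons; it is used consistently for neighbor counts and component
labeling.

Thinning a real junction usually leaves a small *cluster* of bifurcation
voxels rather than a single one, so raw voxel counts would be dominated by
grid artifacts. Two merge rules produce junction *nodes*:

* mutually adjacent (26-connected) bifurcation voxels always form one node;
* two nodes joined by an internal segment shorter than one local vessel
  diameter (twice the largest radius among the bridge and the adjoining node
  voxels) are collapsed into one node, and the bridge voxels are absorbed
  into it (`collapse_short_junctions = TRUE`, the default).

The second rule addresses the *split junction* artifact: a wide branch point
often thins into two bifurcation voxels separated by one or two regular
voxels. A pair of branch points closer together than the vessel is wide is
below the resolution at which a centerline can distinguish them, so counting
them separately reports lattice noise, not anatomy. The same reasoning is
used by vascular graph tools generally. Disable the rule to obtain raw
adjacency-only nodes; the reported `n_bifurcations` counts merged nodes in
either case.

### Radii

The radius at a centerline voxel is the anisotropic Euclidean distance
transform of the mask sampled there — the exact distance (Felzenszwalb–
Huttenlocher separable algorithm, per-axis spacing) from the voxel center to
the nearest *background voxel center*. No half-voxel correction is applied.
This convention is simple and exactly testable (the test suite compares it
with a brute-force nearest-background search to 1e-9), but it reads low by
about half a voxel on average: a 2 mm tube on a 0.5 mm grid measures
≈ 1.8–2.0 mm. Users comparing absolute radii across resolutions should bear
the convention in mind; comparisons *within* a fixed grid (the protocol's
use case) are unaffected.

### Segments and tortuosity

Removing junction nodes disconnects the centerline into maximal simple
paths; each path is one vessel segment. Segment length is the sum of
Euclidean steps between consecutive path points in *world* coordinates, so
oblique affines are handled; the chord is the world distance between the
segment's two ends; tortuosity is length/chord. A closed loop (possible in
masks with touching vessels) has zero chord and an undefined-flagged (`NA`)
tortuosity rather than a division error, as does a single-voxel segment.
Truly isolated voxels (no neighbors at all) form no segment.

A digital path zig-zags around the continuous curve it approximates, which
inflates raw polygonal length by up to ~10% for oblique straight lines. The
length measurement therefore smooths the path with a short symmetric moving
average (default window 5 voxels, shrinking near the fixed ends) before
summing steps. The window is small relative to anatomical curvature: on a
digital semicircle of radius 20 voxels the measured tortuosity is within 1%
of π/2, while an oblique straight line correctly measures ≈ 1 instead of
≈ 1.1. Set `smooth_window = 1` in `path_geometry()` to disable.

Two end effects remain and are documented rather than corrected: thinning
erodes a tube's centerline inward by roughly one tube radius at each open
end, so measured segment lengths under-estimate planted branch lengths by
~2r; and for strongly curved tubes this end erosion slightly lowers
pipeline-level tortuosity (the analytic π/2 semicircle measures ≈ 1.53 at
tube radius 2 mm through the full pipeline, while the centerline-level
measurement above is accurate). Tortuosity analytics in the tests are
therefore asserted at the level the quantity is defined on — the centerline
path — and pipeline-level values are asserted against phantom truth with
end effects accounted for.

## The feature vector

Eleven features summarize a mask: `total_volume_mm3` (foreground voxels ×
|det| of the affine's linear part), `total_length_mm`, `n_segments`,
`n_bifurcations`, `n_endpoints`, `mean/sd/max_radius_mm`,
`mean/sd_tortuosity`, `mean_segment_length_mm`. Conventions: radii at
bifurcation-node voxels are included in radius summaries; undefined
tortuosities are excluded from tortuosity summaries; zero-length
single-voxel segments are excluded from `mean_segment_length_mm`; an empty
mask yields zero counts/volumes and `NA` means, never an error. The set is
configurable (`features =` in `extract_features()`), because the downstream
protocol only fixes the *number* of features (eleven) entering the models,
not their identity; the default set covers every quantity the extractor
defines plus dispersion summaries.

## Phantoms: what they test and what they do not

`make_phantom()` rasterizes analytic curves into tubes (a voxel is
foreground iff its center is within the tube radius of the curve; ends are
clipped flat so a straight tube is a true cylinder whose voxel volume
converges to πr²L under refinement). Kinds: straight tube (tortuosity 1),
circular arc (tortuosity Rθ / (2R sin(θ/2)); π/2 for a semicircle), helix,
Y-tree (1 bifurcation, 3 endpoints), and seeded random binary trees with
branch lengths 10–18 mm, branch angles 25–50°, radii 1–3 mm, on a 128³,
0.5 mm isotropic grid — sized so a phantom plus full feature extraction runs
in ~2 s. Non-adjacent branches are kept more than 4 radii apart by rejection
sampling (sibling far-halves included), the analytic truth records the
planted topology and geometry, and the seed fully determines the tree.
`make_paired_anatomical()` adds a two-level intensity volume with seeded
Gaussian noise for resampling/thresholding plumbing tests.

Phantoms establish that the measurement chain recovers known geometry:
planted bifurcation/endpoint counts exactly in ≥90% of a 20-tree suite,
radii within 15%, per-segment tortuosity within a few percent. They do *not*
emulate real cerebrovasculature: no Circle-of-Willis geometry, no curved or
tapering branches, no touching/kissing vessels, no segmentation noise
(holes, spurs, disconnections), and no MR physics. Passing the phantom suite
therefore validates the *software*, not the biological interpretation of
features extracted from any particular segmentation — in real masks,
segmentation quality is a separate, measurable factor (hence the Dice
metric).

## The statistical protocol

Subject tables carry `age`, `sex`, `diastolic_bp`, `systolic_bp`, `mmse`,
cortical-thickness columns (prefix `ct_`, consumed as given, e.g. one per
atlas region), and the 11 vessel features. The protocol's models are named
formulas (`protocol_formula()`): age regressed on the cortex block, the
vessel block, or both; each dependent variable (blood pressures, MMSE)
regressed on a block plus age and categorical sex; hypertension as logistic
regressions with the same structure.

Conventions, each chosen where a convention was needed and fixed:

* **Listwise deletion**, enforced on the *union* of reduced and full model
  variables in `compare_models()`, so nested fits always use identical rows.
* **Rank deficiency** is an error naming the collinear columns unless
  `allow_aliased = TRUE`; a comparison whose added block contributes no rank
  yields F = 0, p = 1.
* **Nested ANOVA**: F = ((SSR_red − SSR_full)/q)/(SSR_full/(n − p)) with q
  the rank added and n − p the full model's residual df; verified against an
  independent SSR-based oracle to 1e-8 and calibrated (type-I error within
  [0.03, 0.07] at α = 0.05 over 1000 null replicates). For logistic fits the
  same F machinery is applied to deviances — mirroring protocols that reuse
  ANOVA tooling for the logistic comparison — and a likelihood-ratio test is
  reported alongside as a clearly labeled extension.
* **Cross-validation**: subjects are shuffled by a recorded seed into k
  folds (default 10, not stratified); R² = 1 − SS_res/SS_tot over pooled
  out-of-fold predictions, so one value covers the full sample and can be
  negative under the null.
* **Hypertension**: diastolic > 90 mmHg *or* systolic > 140 mmHg, strict
  inequalities — a subject at exactly 90/140 is not labeled. Missing
  pressures yield `NA`, excluded downstream.
* **Age split**: older means strictly above 60 years.
* **No feature standardization** (OLS is affine-equivariant).

`simulate_subjects()` generates tables with known structure for testing and
demonstration: age uniform on 20–88, heterogeneous regional thinning slopes,
vessel features with age trends, blood pressure rising with age. Effect
sizes were set so the vessels-only age model attains a moderate
cross-validated R² (~0.4) and the cortex-plus-vessels comparison shows a
clear but not overwhelming vessel contribution — the regime reported for
vascular morphology in aging cohorts — with hypertension prevalence around
15%. It simulates *linear* trends with Gaussian noise only: no nonlinear
aging trajectories, no feature–feature correlation structure beyond the
shared age signal, no site effects, no missingness.

## Numerical and degenerate-input choices

* Trilinear resampling fills world coordinates outside the source domain
  with 0 (background), appropriate for masks and brain-extracted volumes;
  resampled masks are re-thresholded at 0.5 by convention.
* NIfTI round trips write float64, so voxel values are bit-exact; the affine
  survives the quaternion representation to ~1e-8 mm.
* Empty masks flow through the whole pipeline producing zero counts and
  `NA` means; single-voxel masks classify as endpoints; perfect logistic
  separation is flagged with a warning, not an error; a single-class
  outcome and a zero-variance response are errors.
* Both masks empty defines Dice = 1 (two empty segmentations agree).

## Problem sizes used in the test suite

Unit tests run on 16³–64³ fixtures; the end-to-end suites use the phantom
default of 128³ at 0.5 mm (20 random trees ≈ 50 s), a 96³ cylinder pair for
volume-convergence checks, cohorts of 300–655 simulated subjects for the
model fits, and 1000 replicates for F-test calibration. These sizes were
chosen so the full suite completes in about two minutes while each check
still operates in the regime the method targets.

## Limitations

* Counts and radii are grid-resolution dependent; compare subjects on a
  common grid (the protocol resamples anatomicals to a common resolution
  upstream for exactly this reason).
* The EDT radius convention reads ~half a voxel low; no sub-voxel centerline
  refinement or model-based radius fitting is attempted.
* Masks with many touching vessels produce cycles; these are reported as
  closed segments with undefined tortuosity rather than resolved into
  separate vessels.
* No artery/vein labeling, vascular-territory assignment, or flow modeling.
* The statistical layer fits what it is given: thickness columns are
  consumed as-is, and no multiple-testing correction is applied across
  dependent variables.
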