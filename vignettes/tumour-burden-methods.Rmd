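---
title: "Whole-body PET tumour burden: segmentation, response and method agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-body PET tumour burden: segmentation, response and method agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petburden)
```

## The problem

In metastatic castration-resistant prostate cancer (CRPC), whole-body tumour
burden on ⁶⁸Ga-PSMA PET/CT is a candidate biomarker for monitoring
chemotherapy. Two aggregate quantities summarise it:

* **PSMA-TV** (PSMA-derived tumour volume): the sum of all segmented lesion
  volumes, in cm³;
* **TL-PSMA** (total lesion PSMA): the sum over lesions of
  volume × SUVmean — the tracer-weighted burden. Dimensionally this is
  volume × SUV; because SUV is dimensionless it is conventionally reported
  in cm³.

Different software tools segment lesions differently, so a central question
is whether two tools give *interchangeable* values of these biomarkers, both
statistically (Bland–Altman agreement of the raw numbers) and clinically
(does the therapy-response category change?). This package implements the
whole chain — segmentation, biomarkers, response classification, agreement
statistics — plus a synthetic phantom generator so that every stage can be
tested against known ground truth without patient data.

## Segmentation model

Lesions are segmented by a fixed-threshold isocontour derived from a
normal-tissue reference region:

* **Liver reference** (default): a 3 cm-diameter spherical ROI in healthy
  liver; threshold `1.5 × mean + 2 × SD` over the ROI voxels. We read the
  conventional "3 cm sphere" as a *diameter*, matching PERCIST practice.
* **Aortic reference** (for patients with liver metastases, where the liver
  is unusable): a cylinder of 1 cm diameter and 2 cm z-extent in the
  descending thoracic aorta; threshold `2 × mean + 2 × SD`.

ROI placement is user-supplied coordinates — in clinical practice the
operators place these ROIs manually, and automating liver detection is out
of scope. The choice of reference is an explicit per-patient flag.

Numerical conventions, fixed and documented because they change voxel
counts at boundaries:

* a voxel belongs to an ROI or lesion shape iff its **centre** lies inside
  the shape (boundary inclusive);
* threshold comparison is **inclusive** (`SUV ≥ threshold`);
* connected components use **26-connectivity** in 3D, the common choice in
  PET segmentation;
* components smaller than `min_voxels` are dropped (default 1: no minimum,
  configurable because real analyses discard speck noise);
* lesions are ordered by descending SUVmax with ties broken by ascending
  centroid (x, y, z), so outputs are deterministic;
* structures with physiological tracer uptake (salivary glands, coeliac
  ganglia) are removed via a user-supplied exclusion mask, mirroring the
  expert-reading step that has no algorithmic counterpart.

SUV itself follows the body-weight convention (SUVbw), with the injected
dose decay-corrected to the acquisition start; no uptake-time harmonisation
between timepoints is attempted. Tissue density is taken as 1 g/mL.

## Response classification

Relative change is always *follow-up as a percentage of baseline*,
`ratio = follow_up / baseline × 100`; the signed change often quoted
clinically is `ratio − 100`. Four schemes share one interval logic —
PR if `ratio ≤ pr_max`, PD if `ratio ≥ pd_min`, SD strictly between —
with inclusive boundaries on the PR and PD sides:

| scheme  | input                  | CR                   | PR       | SD            | PD                       |
|---------|------------------------|----------------------|----------|---------------|--------------------------|
| BR      | serum PSA              | PSA undetectable     | ≤ 50%    | 50–125%       | ≥ 125%                   |
| PERCIST | hottest-lesion SUVmax  | no malignant uptake  | ≤ 70%    | 70–130%       | ≥ 130% *or* new lesion   |
| PSMA-TV | whole-body volume      | no measurable burden | ≤ 70%    | 70–130%       | ≥ 130%                   |
| TL-PSMA | whole-body uptake      | no measurable burden | ≤ 70%    | 70–130%       | ≥ 130%                   |

The ±30% cut for the volume biomarkers is a deliberate, pre-registered
convention, not a fitted quantity. Design decisions worth spelling out:

* **PSA-negative disease** (PSA never reflected tumour burden in earlier
  therapy lines) gets **NA**, not CR: the CR cell is reserved for PSA
  falling to undetectable *under therapy*. This matches how such patients
  are handled in practice — BR classification is simply withheld.
* **New lesions** are an input flag from expert reading, not computed;
  a new lesion forces PERCIST-PD regardless of the SUVmax ratio. Because a
  patient can be PD both ways, the cross-tabulation reports two counts:
  patients with any new lesion, and patients whose PD rests on the new
  lesion alone.
* Undefined ratios (zero or missing baseline, e.g. tracer extravasation at
  the baseline scan) yield NA, and NA patients are excluded **pairwise**
  from scheme-agreement counts, not listwise.
* A *relevant* disagreement between two schemes is one scheme calling PD
  while the other does not — the discrepancy that would change management.

## Agreement statistics

Between-method agreement uses Bland–Altman analysis on **relative**
differences, because tumour-volume distributions span orders of magnitude
and absolute differences would be dominated by the largest tumours. The
per-pair quantity is

\[ d_i = \frac{A_i - B_i}{(A_i + B_i)/2} \times 100\% , \]

percent of the pair mean — the standard ratio variant. (The denominator is
a genuine convention choice; `convention = "percent_of_A"` is available as
a sensitivity check.) Summary quantities:

* bias = mean of the `d_i`; limits of agreement = bias ± 1.96 × SD;
* **repeatability coefficient** RC = 1.96 × SD of the relative
  differences — the magnitude below which 95% of between-method differences
  are expected to fall;
* outliers: pairs outside the limits of agreement, computed from **all**
  pairs (no iterative exclusion);
* SD is the sample SD (n − 1) throughout.

Supporting tests wrap the standard R implementations: Spearman rank
correlation (average ranks for ties, asymptotic two-sided p), Wilcoxon
signed-rank (zero differences dropped, exact null for n ≤ 25 without ties,
else normal approximation with continuity correction), Shapiro–Wilk.

The sample-size computation treats the two-method comparison as a paired
design: power of the two-sided one-sample t test on the paired differences
with noncentrality `dz·√n` and `n − 1` degrees of freedom, scanning n
upward. With the conventional large paired effect dz = 0.7, α = 0.05 and
80% power this gives n = 19 — which is also the reading under which the
standard G*Power-style paired-t computation reproduces that number; a
Wilcoxon-based variant (inflating n by the asymptotic relative efficiency)
would be slightly more conservative and is intentionally not the default.

```{r power}
required_sample_size(dz = 0.7, alpha = 0.05, power = 0.80)
```

## The synthetic phantom

`generate_phantom()` builds an axis-aligned SUV volume: uniform background,
one liver-like sphere whose voxels are N(mean, SD) — so the liver reference
has realistic within-ROI variance — and lesions (spheres, ellipsoids, or
boxes for exact-volume tests) at uniform peak SUV. Ground truth is recorded
*before* degradation: lesion volume = count of voxels whose centres lie in
the analytic shape × voxel volume, an exact integer computation.
Degradation is a Gaussian point-spread blur (separable convolution, sigma
in mm, truncated at 4σ with row-renormalised kernels so flat regions stay
flat at volume edges) followed by i.i.d. additive Gaussian voxel noise,
clamped at zero. Default study conditions used throughout the analyses and
tests: 32³ grids at 4 mm isotropic voxels, background SUV 0.5, liver mean
5 / SD 0.3, lesion peaks 9–15, PSF σ 2 mm (matching a typical
post-reconstruction filter), noise SD 0.1.

What the phantom does **not** emulate: attenuation, scatter, reconstruction
artefacts, anatomical variability, inter-timepoint misregistration, or
lesion heterogeneity. Passing phantom-recovery tests therefore shows that
the *algorithmic* chain is correct (thresholding, labelling, aggregation
are exact on ideal data and degrade gracefully under blur/noise); it does
not validate clinical accuracy on real scans, where partial-volume effects
on small lesions — visible already in the blurred phantom condition — are
the dominant error source.

`generate_paired_measurements()` emulates the two-software comparison
directly: log-normal true values (volume-like heavy right tail), relative
differences drawn as Gaussian percentages (optionally with a wider outlier
component), and the second value solved from
`B = A(1 − d/200)/(1 + d/200)` so the generated pair's relative difference
equals `d` *exactly* under the pair-mean convention — making parameter
recovery (bias → bias, RC → 1.96 × SD) a sharp test. A per-pair
relative-difference SD of 20% corresponds to RC ≈ 39%, the scale of
between-software repeatability reported for whole-body PSMA volumetry.

All generators run on a private RNG stream: identical spec + seed gives
bit-identical output and the caller's RNG state is untouched.

## Degenerate inputs and error policy

Empty segmentations are a result (empty lesion table, zero burden), not an
error; "no measurable lesion" only errors where a lesion is structurally
required (hottest-lesion extraction). Reference ROIs that leave the volume
or cover fewer than 10 voxels error immediately — a silently truncated ROI
would bias the threshold. In the study pipeline, per-patient problems (PSA
negativity, undefined ratios) propagate NA with a warning and the run
continues, since dropping a whole cohort for one bad baseline scan would be
wrong.

## Known limitations

* Reference-ROI placement is manual by design; no anatomical segmentation.
* No lesion tracking across timepoints: response uses aggregate burden and
  the per-timepoint hottest lesion, as the classification schemes require.
* The Bland–Altman machinery is the simple two-method, one-measurement
  variant; repeated-measures or regression-based limits are out of scope.
* TL-PSMA is reported in cm³ by convention although it is volume × SUV.
* Survival columns in the bundled cohort data are pass-through metadata;
  no survival modelling is attempted.
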