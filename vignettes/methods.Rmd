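---
title: "Regional colocalization of amyloid PET and cortical superficial siderosis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional colocalization of amyloid PET and cortical superficial siderosis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Cerebral amyloid angiopathy (CAA) deposits beta-amyloid in cortical and
leptomeningeal vessels, making them fragile; prior subarachnoid bleeding
leaves linear hemosiderin traces along gyri and sulci — cortical superficial
siderosis (cSS), visible on GRE-T2\*-weighted MRI. If regionally pronounced
amyloid load made vessels locally more vulnerable, cSS and amyloid-PET
positivity should colocalize across cortical regions. petcoloc implements an
atlas-based pipeline to test that hypothesis: from a binary cSS segmentation,
an amyloid-PET image and a label parcellation (all co-registered on one
voxel grid), it derives per-region cSS and amyloid status, SUVr in
cSS-defined voxel strata, and the concordance, rank-correlation and paired
comparison statistics.

Registration, bias-field correction, rater segmentation and partial-volume
correction are upstream of this package and out of scope: inputs are assumed
co-registered on a common grid, and grids that differ are rejected rather
than resampled.

## Pipeline and assumptions

1. **Smoothing** (`smooth_mask()`): the binary segmentation is convolved
   with a separable Gaussian to emulate the effective PET resolution. The
   5 mm width is interpreted as full-width-at-half-maximum (the PET
   convention), so sigma = 5 / (2 sqrt(2 ln 2)) ≈ 2.123 mm; a
   sigma-interpretation is available via `interpretation = "sigma"`. The
   kernel is truncated at 4 sigma and renormalized; edges are zero-padded
   and the result clipped to [0, 1], so solid interior masks keep value 1.
2. **Region classification** (`classify_css_regions()`): a cortical VOI is
   cSS-positive when the smoothed map reaches 0.90 anywhere inside it. The
   90% criterion could also be read as a volume-fraction rule; the max-rule
   is the default because it is the only reading consistent with applying
   the same smoothed map at both the 0.9 and the 0.1 cutoff, and the
   fraction rule is exposed as `rule = "fraction"`. Both thresholds are
   inclusive (`>=`). Within a positive VOI, voxels with smoothed value
   >= 0.1 form the direct-siderosis stratum (cSS+1) and the remainder the
   surrounding stratum (cSS+0); the two strata partition the VOI exactly.
3. **Controls** (`assign_contralateral_controls()`): a cSS-positive VOI
   receives its contralateral homolog as control region iff the homolog is
   itself cSS-negative.
4. **Quantification** (`compute_suvr()`): SUVr is activity divided by the
   cerebellar reference, the unweighted mean of the left and right
   cerebellar VOI means (a pooled-voxel option exists for unequal VOI
   sizes). Dose and body weight cancel in the ratio. SUVr is computed for
   the whole VOI, both strata, and the control region.
5. **Amyloid classification** (`build_hc_reference()`, `classify_ab()`):
   healthy controls are screened once, leave-one-out: a control is excluded
   a priori if in any region its SUVr exceeds the other controls' mean by
   more than 2.5 of their SDs (one-sided — the screen removes early amyloid
   accumulators, never low outliers). The screen is a single pass, not
   iterated: "a priori" describes one screening of the candidate pool.
   A patient region is amyloid-positive when its SUVr reaches MV + 2.5 SD
   of the retained controls (inclusive). The 2.0-SD variant is accepted in
   the configuration; 2.5 is the default because it is the operational
   (Methods-section) value.
6. **Statistics** (`coloc` functions): per-region positivity frequencies
   are rank-correlated (average ranks, two-sided p from the t
   approximation); all 600 (patient, region) cells are cross-tabulated and
   compared with the independence expectation (row x column / N); stratum
   SUVr are compared with dependent-samples t-tests pooling
   (patient, region) units within each lobe family — composite = frontal +
   temporal + parietal + posterior cingulate; occipital is not a standard
   amyloid target region and is excluded. Each lobe's four raw p-values are
   Benjamini–Hochberg adjusted within the family, multiplied by 5
   (Bonferroni across the five lobe analyses) and capped at 1. The
   adjusted-p (min-over-steps) formulation of BH is used precisely so a
   single number per contrast can be multiplied and capped.

Demographics use the unequal-variance (Welch) t by default: the pooled form
gives p ≈ 0.042 for the published age comparison whereas Welch reproduces
the printed 0.073 (and 0.148 / 0.775 / 0.759 for the subgroup rows); a
`welch = FALSE` option provides the pooled form. The sex chi-square is
Pearson without continuity correction (reproducing the printed 0.020);
Yates' correction is available as an option.

## The phantom generator

No imaging data are distributed with the study, so the package ships a
phantom cohort generator (`phantom_config()`, `simulate_cohort()`) whose
defaults are the study conditions: 10 patients and 14 controls on a
64 x 64 x 48 grid at 2 mm spacing, 60 cortical VOIs (26 frontal,
20 temporal, 6 parietal, 6 occipital, 2 posterior cingulate; 30 per
hemisphere with mirror homologs) plus left/right cerebellum.

**Atlas.** `make_atlas()` builds two mirror-symmetric lateral cortical
plates (the interior is unlabeled), each partitioned into 30 cuboid blocks
on a 6 x 5 anterior–posterior by inferior–superior grid, with lobes
assigned to reproduce the standard composition; the cerebellar VOIs occupy
an inferior slab. This is a block model of cortical grey matter, not an
anatomical shell — the downstream mathematics only ever sees labels and
voxel sets.

**Healthy-control signal model.** A region's activity for subject *h* is
`hc_mean + g_h + e_hr` plus iid voxel noise, with the cerebellum pinned at
the reference level so true SUVr is known. The marginal across-subject SD
`hc_region_sd` defaults to 0.095 so HC SUVr is approximately N(1.3, 0.1)
and the positivity threshold sits near 1.55, commensurate with the SUVr
scale of florbetaben PET. A fraction `subject_rho` (default 0.9) of that
variance is carried by the shared per-subject effect `g_h`: real amyloid-PET
regional SUVr are strongly correlated within a subject, and this structure
is what keeps the a-priori control screen selective — with 60 *independent*
region effects, the probability that a control exceeds 2.5 SD somewhere
would approach 60% per subject and the screen would gut the cohort.

**Siderosis geometry.** Each affected region receives two crossing
6-mm-thick line segments through its centroid (thickness
`css_line_thickness_mm`, matching the segmentation brush), clipped to the
region — siderosis tracing the two banks of a sulcus. The crossing matters
numerically: a single 6 mm slab smoothed at FWHM 5 mm peaks at about 0.86
and would never reach the 0.90 threshold, while the union of two orthogonal
slabs peaks near 0.98, so planted regions are detected exactly and
neighbouring regions (peak spill-over ≈ 0.3) are not. The default per-patient
region counts (1, 2, 2, 3, 13, 20, 25, 30, 35, 39) mirror a cohort of four
focal (≤ 3 regions) and six disseminated patients totalling 170 affected
regions.

**Amyloid truth and coupling.** Each cortical region is planted
amyloid-positive with probability `p_ab` (default 0.6, reproducing the
observed ~37/60 positive regions per patient); planted regions' activity is
scaled by `ab_effect` (default 1.4, a ~5.5 SD elevation). The coupling
parameter `coloc_rho` raises the conditional probability for siderosis
regions to `p_ab + coloc_rho (1 - p_ab)`: 0 gives exact independence (the
study's null finding, and the default), 1 nests siderosis inside amyloid.
An optional `css1_deficit` subtracts a fixed SUVr amount from the
direct-siderosis stratum, emulating the reduced uptake the study observed
at cSS sites.

**Reproducibility.** Every subject draws from an RNG stream derived from
(master seed, subject index), so cohorts are bitwise reproducible and stable
under subsetting. `write_cohort()` emits all volumes (NIfTI), tables, the
resolved configuration and an MD5 manifest; `verify_manifest()` detects
tampering.

**What the phantom does not emulate.** PET point-spread and reconstruction,
scanner harmonization, attenuation, anatomical sulcal geometry, atrophy and
partial-volume effects, and protocol heterogeneity between MRI matrices.
Passing tests on phantoms therefore validate the pipeline's mathematics and
calibration, not its behaviour under real acquisition physics.

## Numerical choices and degenerate inputs

- Spacing comparisons tolerate 1e-4 mm; orientation or shape differences
  are errors, never resampled.
- Volumes are written as 64-bit floats so round trips are bit-exact.
- Empty voxel strata raise an "empty stratum" error; a VOI fully covered by
  the smoothed map (no cSS+0 voxels) reports that stratum as missing.
- Paired tests flag zero-variance differences (including a constant
  nonzero shift) as degenerate instead of dividing by zero; the constant's
  sign is reported.
- A constant frequency vector leaves the rank correlation undefined and
  flagged.
- Lobes with no eligible regions (the posterior cingulate control column,
  for instance) report n.a. throughout.
- `overlap_pct` is kept at full precision internally and rounded only in
  reports.

## Calibration properties and their problem sizes

Three simulation studies back the statistical claims; their sizes are the
package's choices and are exercised in the test suite:

- **Null calibration:** 200 cohorts with `coloc_rho = 0` and no stratum
  effect; every composite-lobe contrast's adjusted-p < 0.05 rate stays at
  or below 5%, and observed minus expected concordance is centred on zero
  (within 3 Monte-Carlo SEs).
- **Power:** 100 cohorts with a planted direct-siderosis SUVr deficit of
  0.08 (the composite effect size reported for the study); the
  cSS+1-vs-cSS+0 contrast reaches adjusted p < 0.05 in at least 80% of
  cohorts at ~150 pooled regions.
- **Classifier recovery:** with ≥ 5-SD planted elevations the classifier
  recovers ≥ 95% of planted regions (pooled over 10 default cohorts).

A finite-sample property worth knowing: with only 14 controls, the
MV + 2.5 SD threshold is itself estimated, and the marginal false-positive
rate for a control-like region is bounded below by
P(t₁₃ > 2.5 · sqrt(14/15)) ≈ 1.6% — noticeably above the asymptotic
Φ(−2.5) ≈ 0.6% — and the a-priori screen, by trimming the upper tail of the
control pool, lowers the threshold further. The classifier's intrinsic
error rates are therefore tested against a large control pool, where the
normal-tail oracle applies; under study-sized references, occasional
whole-patient false-positive clusters (a genuinely high-uptake subject
crossing the absolute threshold everywhere) are expected behaviour of the
method, not a defect of the implementation.

## Known limitations

- The focal/disseminated split uses a region-count proxy (≤ 3 vs > 3
  cSS-positive regions) for the clinical sulcus-count rule.
- The pipeline performs no within-patient aggregation in the stratum
  comparisons: the sampling unit is the (patient, region) pair, mirroring
  the published n's (151 composite = 78 + 35 + 32 + 6); correlated
  observations within a patient are not modelled (no mixed effects).
- The temporal-exclusion sensitivity analysis is a subset rerun of the rank
  correlation; it carries no separate numeric target.
- The 90%-threshold reading (max rule vs volume fraction) is genuinely
  ambiguous; both are implemented, max rule default, and results that
  depend on the choice should be reported with both.

## A worked example

```{r, eval = FALSE}
library(petcoloc)

cfg <- validate_config(config = list(seed = 1))
run <- cohort_analysis(cfg)
run                      # cohort overview
summary(run$matrix)      # per-patient positivity and overlap
glance(run$concordance)  # 2x2 margins and independence expectation
run$lobes                # stratum comparisons with adjusted p-values
autoplot(run$matrix)     # classifier grid
plot_frequency_scatter(run$matrix)
```
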