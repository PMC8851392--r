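# petcoloc

Regional colocalization analysis of amyloid-PET positivity and cortical
superficial siderosis (cSS) in cerebral amyloid angiopathy (CAA).

## The problem

CAA deposits beta-amyloid in cortical and leptomeningeal vessels; the
resulting vessel fragility leaves linear hemosiderin traces along gyri and
sulci (cSS) on GRE-T2\*-weighted MRI. If high regional amyloid load made
vessels locally vulnerable, amyloid-PET positivity and cSS should occupy the
same cortical regions. petcoloc is for imaging researchers who want to test
that hypothesis quantitatively: it takes a co-registered binary cSS
segmentation, an amyloid-PET volume and an atlas parcellation, and produces
region-level biomarker statuses, stratum-level SUVr and the full set of
concordance statistics — plus a phantom cohort generator with known ground
truth, so the entire pipeline is testable without patient data.

## The method

For each of 60 cortical atlas VOIs (26 frontal, 20 temporal, 6 parietal,
6 occipital, 2 posterior cingulate):

- the binary cSS segmentation is smoothed with a 5 mm FWHM Gaussian into a
  probability map; a VOI is **cSS⊕** when the map reaches 0.90 inside it,
  and its voxels split into a direct-siderosis stratum **cSS⊕1** (map ≥ 0.1)
  and a surrounding stratum **cSS⊕0**;
- SUVr = VOI mean activity / cerebellar reference (mean of the left and
  right cerebellar VOI means);
- a VOI is **Aβ⊕** when SUVr ≥ MV + 2.5 SD of a healthy-control cohort,
  after a one-pass leave-one-out screen that excludes controls lying more
  than 2.5 SD above the other controls in any region;
- colocalization is then tested three ways: Spearman correlation of
  per-region positivity frequencies, the 2×2 concordance table of all
  (patient, region) cells against its independence expectation
  (row × column / N), and dependent-samples t-tests between cSS⊕ / cSS⊕1 /
  cSS⊕0 / contralateral-control SUVr, pooled per lobe, with
  Benjamini–Hochberg adjustment within each lobe family and a ×5 Bonferroni
  factor across lobes (capped at 1).

See `vignettes/methods.Rmd` for the model details, generator design and
numerical conventions.

## Worked example

```r
library(petcoloc)

cfg <- validate_config(config = list(seed = 1))  # default phantom cohort
run <- cohort_analysis(cfg)
run
#> <petcoloc_run> 10 patients x 60 regions (seed 1)
#>   amyloid+ cells 371, cSS+ cells 170, mean overlap 52.9%
#>   spearman rs = 0.033 (p = 0.802); concordant 105 vs 105.1 expected
```

The default phantom plants 170 siderosis regions with **no**
siderosis–amyloid coupling (`coloc_rho = 0`), and the run shows exactly
that: the rank correlation is near zero and the 105 doubly-positive regions
match the 105.1 expected under independence. Per-patient summaries mirror
the multiregion-classifier bookkeeping:

```r
summary(run$matrix)
#> # A tibble: 10 x 4
#>   patient_id n_ab_pos n_css_pos overlap_pct
#> 1 CAA01            34         1         0
#> 2 CAA02            29         2        50
#> 3 CAA03            41         2        50
#> ...
```

`run$lobes` holds the stratum comparisons with adjusted p-values,
`autoplot(run$matrix)` draws the patients × regions classifier grid, and
`plot_frequency_scatter(run$matrix)` the per-region frequency scatter.
Setting `coloc_rho` near 1 or a nonzero `css1_deficit` plants the effects
the statistics are designed to detect. `write_cohort()` materialises a
cohort (NIfTI volumes, tables, checksummed manifest) for use outside R, and
`inst/scripts/petcoloc.R` wraps simulate/run/batch for the shell.

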