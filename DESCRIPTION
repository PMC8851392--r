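Package: petcoloc
Title: Regional Colocalization of Amyloid-PET Positivity and Cortical
    Superficial Siderosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Atlas-based pipeline for testing whether cortical superficial
    siderosis (cSS) and beta-amyloid PET positivity are regionally
    colocalized in cerebral amyloid angiopathy. Smooths binary cSS
    segmentations into probability maps, classifies atlas volumes of
    interest as cSS-positive, partitions them into direct-siderosis and
    surrounding voxel strata, computes cerebellum-referenced SUVr per
    stratum, derives amyloid positivity from a healthy-control reference
    with a-priori outlier screening, and runs the concordance, rank
    correlation and lobe-wise paired comparisons with hierarchical
    FDR-plus-Bonferroni correction. Includes a synthetic phantom cohort
    generator with known ground truth and tunable cSS-amyloid coupling so
    the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
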