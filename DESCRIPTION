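Package: dotfrac
Title: Cerebellar Grey-Matter Dot-Fraction Mapping from Spherically Encoded Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates cerebellar grey-matter microstructure from ultra-high-b
    spherical-tensor-encoded (STE) diffusion MRI. Per voxel, a mono-exponential
    fit to the high-b signal yields the sphere ("dot") compartment signal S0s and
    diffusivity Ds, and a bi-exponential free-water-elimination fit to the low-b
    signal yields the tissue fraction ft, tissue mean diffusivity MD and S0; the
    sphere signal fraction is fs = S0s/(ft*S0). Includes Rician noise-floor and
    temporal drift correction, robust outlier exclusion, lobule/lobe ROI
    aggregation with the voxel-inclusion filters used for cerebellar grey matter,
    group statistics (Mann-Whitney, ICC(2,1), covariate-adjusted regression,
    one-way ANOVA with Tukey post-hoc, Bonferroni thresholds), and a synthetic
    phantom/cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
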