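Package: growthtrack
Title: Quantifying Tumor Growth Direction Relative to White-Matter
    Microstructure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the direction of contrast-enhancing tumor
    growth between two imaging timepoints relative to white-matter
    microstructure from a diffusion-tensor template. Implements affine and
    B-spline free-form deformable registration of tumor masks on signed
    distance maps, principal-eigenvector and fractional-anisotropy maps
    from tensor volumes, voxel-wise growth-to-fiber angle histograms in
    nine 10-degree bins with parallel (0-20 degree) and perpendicular
    (70-90 degree) summary fractions, cohort statistics (paired t-test
    with Cohen's d, Lilliefors normality, one-way ANOVA, tumor frequency
    maps), and a synthetic phantom generator with analytic ground-truth
    deformation fields for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    nortest,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
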