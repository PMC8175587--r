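Package: retroughness
Title: Roughness of Retinal Layer Thickness Maps by Box-Counting Fractal
    Dimension
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the surface roughness of retinal layers from
    optical coherence tomography (OCT) boundary-surface stacks.  Converts
    the eleven segmented boundary surfaces of the macular volume into
    tilt-corrected per-layer thickness maps, spatially normalizes them to
    a canonical maculopapillary frame, extracts the central foveal region
    of interest, and estimates each map's roughness as the grayscale
    differential box-counting fractal dimension (classic and integer-ratio
    border variants, two thickness codings).  Includes the cohort-level
    inference used to evaluate layer roughness as an Alzheimer's disease
    biomarker (exact Mann-Whitney rank-sum tests, paired and independent t
    tests, Shapiro-Wilk, variance-ratio and Kolmogorov-Smirnov checks,
    one-sided Pearson correlation matrices, principal components and
    maximum-likelihood two-factor models with KMO and Bartlett
    diagnostics) and a synthetic-cohort generator based on spectrally
    synthesized fractional Brownian surfaces with known theoretical
    fractal dimension.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
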