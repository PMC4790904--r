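Package: roisum
Title: Single-Value Summary Measures for fMRI Regions of Interest
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking single-value summary measures of task fMRI
    activation within regions of interest (ROIs). Provides a synthetic BOLD
    cohort simulator with known group effects, per-voxel first-level GLM
    fitting, three ROI definition strategies (sphere, anatomical mask,
    task-activated joint cluster), ten ROI summary measures (mean, median,
    eigenimage-weighted mean, top-percentile, peak, top-N contiguous voxels,
    peak sphere, peak-correlated voxels, peak cluster mean and extent) in
    unthresholded and voxel-p-thresholded variants, group comparisons with
    Cohen's d and omega squared effect sizes, covariate-matched resampling,
    and a permutation test of between-group peak localization differences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    stats,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
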