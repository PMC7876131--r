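Package: powerstate
Title: Brain-State Classification from fMRI Degree-Distribution Power Laws
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes 4D resting-state fMRI volumes into degree distributions of
    the thresholded Pearson-correlation voxel network, fits single and broken
    (double) power laws with AIC model selection, selects discriminative degree
    bins by two-phase chi-squared (ChiMerge-style) discretization, classifies
    anesthesia/strain states with a C4.5 decision tree under stratified tenfold
    cross-validation, and models state-to-state transitions with a ridge
    linear-regression transformation matrix. Includes synthetic-data generators
    (power-law degree cohorts and planted-cluster 4D volumes), voxel-network
    graph metrics (shortest-path length and clustering coefficient), and a
    reproducible end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    pROC,
    RNifti,
    jsonlite,
    MASS
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
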