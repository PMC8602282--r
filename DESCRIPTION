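Package: mbtemporal
Title: Longitudinal Quantitative Microbiome Profiling and Temporal
    Variability Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for dense longitudinal gut microbiome time series with
    absolute quantification. Builds quantitative microbiome profiles (QMP)
    from 16S read counts, rRNA gene copy numbers and flow-cytometric cell
    counts via depth-optimised copy-number-corrected rarefaction; quantifies
    within- versus between-subject variation (intraclass correlation,
    coefficients of variation, fold changes, Taylor's law, augmented
    Dickey-Fuller stationarity, median-abundance error curves); classifies
    temporal core, persistent, transient and person-specific genera;
    analyses community structure (Bray-Curtis dissimilarity, principal
    coordinates, multivariate dispersion, similarity decay); fits Dirichlet
    multinomial mixture enterotypes against a cross-sectional background
    and screens for mislabelled samples; models enterotype transitions with
    a continuous-time Markov model with covariates; and derives host
    covariates (energy intake, personal dietary lag, menstrual-cycle
    hormone profiles). A synthetic-cohort generator with ground truth makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, vegan, jsonlite, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), mclust, withr, optparse, biomformat
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Microbiome, Metagenomics, TimeCourse, Software
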