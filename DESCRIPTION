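Package: salivaRaman
Title: Raman Hyperspectral Saliva Chemometrics for Dry-Mouth Diagnostics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Chemometric workflow for classifying donors from Raman
    hyperspectral maps of dried saliva drops, aimed at separating Sjogren's
    disease from radiation-induced xerostomia and healthy controls. Provides
    an S4 container for spectral datasets built on SummarizedExperiment,
    a synthetic saliva-spectrum simulator, the preprocessing chain
    (asymmetric weighted least-squares baseline, amide-I band normalization,
    Savitzky-Golay smoothing), Hotelling T-squared outlier removal in PLS-DA
    score space, genetic-algorithm wavelength selection driven by PLS
    cross-validated prediction error, an RBF-kernel SVM discriminant
    classifier on PLS-compressed scores, custom cross-validation with
    per-class performance metrics, and spectral-to-donor majority voting.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    signal,
    e1071,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
LinkingTo: Rcpp, RcppArmadillo
RoxygenNote: 7.3.3
biocViews: Classification, Spectrometry, Software
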