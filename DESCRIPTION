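Package: rdnad
Title: Reliability-Density Neighbourhood Applicability Domains for Binary QSAR Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising the applicability domain (AD) of binary
    QSAR classifiers from precomputed molecular descriptor tables. Implements
    the reliability-density neighbourhood (RDN) method, in which per-instance
    k-nearest-neighbour density thresholds (bounded by the Tukey outlier
    fence) are corrected by an ensemble reliability weight combining
    precision (one minus ensemble standard deviation) and bias (agreement
    with the observed class). Also provides the unweighted density k-NN AD,
    ensemble standard-deviation tiers, a kernel-density AD on the first
    principal component, an AD-robustness scoring function comparing
    accuracy-versus-coverage profiles of two external sets, ReliefF feature
    weighting for AD-specific descriptor selection, and a synthetic-data
    generator with planted density and reliability structure for testing.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
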