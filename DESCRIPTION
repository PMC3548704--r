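Package: crocval
Title: Distance-Function Benchmarking for Clustering via the BMI Index and
    CROC Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess the intrinsic discriminative ability of a
    distance function for clustering, with gene-expression data as the
    motivating use case. Partitions and thresholded distance matrices are
    mapped onto the ROC plane through pair-level co-clustering confusion
    counts; threshold graphs are closed into proper partitions via connected
    components, yielding the Corrected ROC (CROC) curve of a distance
    function and its area under the curve. Solutions are scored with the
    Balanced Misclassification Index (BMI) and compared against classical
    external indices (adjusted Rand, Fowlkes-Mallows, F-measure) and against
    K-means and hierarchical clustering solutions. Includes seeded generators
    for three benchmark simulated gene-expression datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
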