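Package: fluencynet
Title: Correlation-Based Semantic Networks from Verbal Fluency Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and compares group-level semantic networks from timed
    category verbal-fluency responses. Per-subject word lists are coded as
    binary subject-by-word incidence matrices, word-word association is
    measured with the phi (Pearson) correlation between response profiles,
    and the complete correlation network is filtered to its Planar Maximally
    Filtered Graph (PMFG) and binarized. Small-world summary statistics
    (average shortest path length, diameter, clustering coefficient, mean
    degree, small-world-ness) are computed against matched Erdos-Renyi
    references, group differences are assessed with Erdos-Renyi null
    distributions and bootstrapped partial-network comparisons, and word
    importance is scored by leave-one-word-out network re-estimation. A
    clustering-and-switching generator produces synthetic two-group fluency
    datasets with planted subcategory structure for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
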