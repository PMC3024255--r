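Package: netpreserve
Title: Module Preservation Statistics for Weighted Correlation Networks
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical assessment of whether a network module defined in a
    reference weighted network (or expression data set) is preserved in an
    independent test network. Implements density-, connectivity- and
    separability-based preservation statistics for general adjacency-specified
    networks and for correlation (co-expression) networks, permutation Z
    statistics with composite summaries (Zsummary, Zsummary.adj, medianRank,
    summary log10 p-values), module quality statistics, cross-tabulation
    statistics (co-clustering, Fisher overlap tests), and a synthetic
    paired-network generator covering seven benchmark simulation scenarios
    with a grading harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
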