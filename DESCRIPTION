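Package: phasenet
Title: Directed Gene Regulatory Network Inference from Short Expression
    Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Supervised inference of directed genetic regulatory networks
    from short, equally sampled microarray time series. Pairwise gene
    candidates are scored by binned mutual information, Pearson correlation
    with exact t-based significance, and a combined associativity measure;
    candidates are partitioned into authentic, questionable and unauthentic
    groups by an iterative centroid-initialised thresholding criterion
    embedded in a small multiobjective combinatorial-optimization wrapper
    that accepts prior-knowledge constraints; regulatory direction per pair
    is called from the phase of the Welch-estimated cross-spectral transfer
    function under a gain threshold. Includes a ground-truthed synthetic
    time-series generator, delimited-table I/O, and SIF/GraphML/edge-table
    network export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
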