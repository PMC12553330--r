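Package: clonetrack
Title: Dominant Clonal Lineages from DNA Barcode Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies dominant clonal lineages in high-resolution DNA
    barcode lineage-tracking experiments. Barcode frequency trajectories are
    filtered for noise, summarised with Hill-number effective diversity,
    compared pairwise by Pearson correlation or dynamic time warping, grouped
    by agglomerative (UPGMA/UPGMC) hierarchical clustering, and summarised as
    LOESS consensus "clonal clusters" ranked by final abundance. A forward
    Wright-Fisher simulator of barcoded populations with de novo beneficial
    mutations generates ground-truth benchmarks for validating cluster
    recovery against known lineage fitness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    ggplot2,
    ape,
    mclust,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse,
    withr
Config/testthat/edition: 3
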