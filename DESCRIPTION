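Package: xregenrich
Title: Width-Matched Permutation Tests for Non-Coding Element Enrichment
    in Chromosome-X Region Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether disease-associated genomic regions on a single
    chromosome are enriched for annotation elements (lncRNAs, circRNAs,
    miRNAs, superenhancers) using a permutation null of randomly placed
    region sets that preserve the query's region count and width multiset.
    Builds query regions from SNP association tables at a nominal p-value
    threshold, counts elements partially or totally overlapping the
    regions, derives empirical p-values as the fraction of randomized
    iterations with the same or a larger count, and runs a bootstrap
    gene-set enrichment test of candidate genes against a curated
    differentially-methylated gene list. A synthetic-data generator with
    exactly planted truths makes every stage testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
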