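Package: igdist
Title: Genome Rearrangement Distances with Intergenic Regions and Repeated Genes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Rearrangement distance estimation between balanced, co-tailed
    genomes represented as a gene string together with intergenic region
    sizes, allowing duplicated genes. Implements the direct and reverse
    minimum common intergenic string partition problems (MCISP/RMCISP) with
    a 2k-approximation (k being the maximum gene multiplicity), exact
    small-instance partition and breadth-first-search distance oracles,
    constructive sorting by intergenic transpositions and/or reversals
    meeting partition-based upper bounds, partition-based lower bounds,
    orthologous assignment sampling, and a simulation pipeline for
    benchmarking distance estimates on randomly rearranged genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
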