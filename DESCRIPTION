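Package: refdbkit
Title: Build and Benchmark Curated Region-Specific 16S rRNA Reference Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to construct curated, taxonomy-unified 16S rRNA reference
    databases from arbitrary FASTA/TSV source databases and to benchmark
    taxonomic classifiers against in-silico mock communities. Supports
    NCBI-style synonym unification, quality filters for unknown or
    rank-sparse annotations, a reference/candidate merging algorithm with
    substring-aware duplicate detection, degenerate-primer extraction of
    hypervariable regions (V4, V1-V3, V3-V4, V3-V5), dereplication,
    100 percent identity clustering with merged ("clustered") nomenclature,
    mock community generation with simulated classifier output, and
    evaluation via abundance-weighted multi-class confusion-matrix metrics
    and Bray-Curtis distances.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    vegan,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
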