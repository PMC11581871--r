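Package: dualmapsim
Title: Simulation and Benchmarking of Read Separation for Dual RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to benchmark in silico separation of mixed host and
    parasite transcriptome reads in dual RNA-seq experiments. Simulates a
    host/parasite genome pair with controlled homologous divergence,
    within-genome paralogy and ultra-conserved loci, generates paired-end
    read libraries with ground-truth origin, assigns reads by sequential
    (either order) or combined (concatenated-reference) competitive
    mapping under multimap and mismatch caps, labels every read pair with
    a truth-aware taxonomy, quantifies one-side and two-side
    cross-mapping, and computes precision, sensitivity, specificity and
    accuracy together with replicate-averaged report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
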