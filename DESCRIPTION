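Package: mitokit
Title: Comparative Analysis Toolkit for Plant Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the downstream comparative analysis of assembled
    plant mitochondrial genomes: iterative organelle read baiting from
    long-read pools, repeat landscapes (microsatellites, tandem repeats and
    dispersed repeats), relative synonymous codon usage, C-to-U RNA-editing
    site calling with hydropathy-effect classification, LWL/MLWL Ka/Ks and
    nucleotide diversity, and detection of mitochondrion-plastid homologous
    fragments. A fully specified synthetic-data generator emits every input
    the pipeline consumes together with machine-readable ground truth, so
    each stage can be exercised and benchmarked without any external
    download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    data.table,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
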