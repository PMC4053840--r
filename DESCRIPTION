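Package: fourCarch
Title: Circular Chromosome Conformation Capture (4C) Interactome and
    Chromosome Architecture Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable analysis pipeline for circular chromosome
    conformation capture (4C-seq) experiments: in-silico restriction
    digestion and fragment-map annotation, primer demultiplexing and
    exact-match read mapping with fragment-end counting and fractional
    multiread allocation, fragment-window interaction values with
    per-arm shuffle-null P-values and prey calling, chromosome
    architecture statistics (contact distance-decay exponent, arm-class
    read shares, centromere-distance regressions, replicate
    correlation/clustering), and epigenome-interactome integration
    (per-fragment epigenetic modification densities, prey/control
    permutation tests, a GSEA-like enrichment score, Benjamini-Hochberg
    FDR). A synthetic-data module generates genomes, viewpoint-anchored
    reads with power-law cis decay and planted enriched prey windows,
    and chromatin-state-dependent feature tracks with truth tables, so
    the full pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
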