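Package: spaninscan
Title: Discovery and Classification of Bacteriophage Spanin Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies the lysis genes that disrupt the Gram-negative outer
    membrane (spanins) in bacteriophage genomes. Enumerates open reading
    frames in all six frames including genes nested in alternate reading
    frames of annotated coding sequences, refines start codons using
    Shine-Dalgarno and membrane-localization signal evidence, types proteins
    as i-spanin, o-spanin or unimolecular spanin candidates from
    Kyte-Doolittle transmembrane hydropathy and lipoprotein lipobox motifs,
    classifies gene-pair architecture (embedded, overlapped, separated) and
    reading-frame relationships, clusters periplasmic domains into families
    by identity and coverage thresholds, and summarizes cysteine and lipobox
    statistics. Includes a synthetic phage-genome simulator with planted
    spanin systems so every pipeline stage can be benchmarked against a
    known truth table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    BiocGenerics,
    S4Vectors,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
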