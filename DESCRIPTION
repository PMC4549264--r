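Package: nucarch
Title: Nucleosome Architecture Analysis for Mononucleosomal Fragment Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing nucleosome organization from MNase-seq
    mononucleosomal fragment intervals: per-base nucleosome occupancy score
    (NOS) tracks, nucleosome calling with a minimum dyad spacing,
    dyad-relative mono- and dinucleotide frequency profiles with FFT
    periodicity estimation, genome-wide phasing spectra, strand-aware
    feature-centred metaprofiles with k-means clustering of promoter
    architectures, DNA methylation to nucleosome-dyad geometry with rank
    statistics, and detection of enhancer-like nucleosome-depleted regions
    flanked by well-positioned nucleosomes. A fully parameterised
    synthetic-data generator with ground truth supports end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    BiocGenerics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
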