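Package: uvspectra
Title: UV-Induced Mutation Spectra, Transcriptional Strand Asymmetry, and
    Photoproduct Damage Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analyzing ultraviolet-light mutagenesis from somatic
    mutation catalogs. Reads and filters per-isolate mutation tables, merges
    adjacent substitutions into tandem and triple events, and normalizes
    single substitutions to the pyrimidine-strand convention with
    trinucleotide context and dipyrimidine categories. Builds 96-class
    trinucleotide spectra, tandem spectra, and flanking-base frequency
    matrices; compares strains per mutation class with Welch t-tests under
    Holm-Sidak step-down correction. Computes transcriptional asymmetry as
    trinucleotide-frequency-normalized non-transcribed over transcribed
    strand ratios with chi-square tests, Bonferroni correction, count
    thresholds, gene exclusions, and expression-quartile stratification.
    Converts UV damage endonuclease sequencing (UVDE-seq) read positions to
    dinucleotide lesion sites and compares treated against control samples.
    Implements reporter mutation and reversion frequency formulas with the
    zero-count maximum-estimate convention, cohort frequency ratios, and
    recurrent-mutation odds ratios from sample tables. A forward simulator
    of the lesion, repair, and translesion-bypass process generates genomes,
    gene annotations, mutation tables, damage reads, and cancer sample
    tables with full truth bookkeeping, so every analysis stage can be
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    BiocGenerics,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
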