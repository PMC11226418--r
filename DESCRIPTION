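Package: emsift
Title: Discovery and Characterization of EMS-Induced SNPs in Mutagenized Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies single-nucleotide mutations induced by ethyl
    methanesulfonate (EMS) in a resequenced mutant population by filtering a
    multi-sample variant call set against wild-type controls and a reference
    genome, then characterizes the retained mutations: per-chromosome mutation
    frequencies (SNPs/Mb), transition/transversion substitution spectra,
    functional effect classes derived from gene models (synonymous,
    non-synonymous, stop-gain, intron, upstream/downstream, intergenic),
    linear models of mutation count against chromosome length, dendrogram
    comparison with an entanglement score, and hypergeometric GO term
    over-representation with Benjamini-Hochberg correction. A synthetic-study
    simulator with known ground truth (reference genome, gene models,
    wild-type background, per-mutant EMS mutations) supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    vcfR,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    methods,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
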