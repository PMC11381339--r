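Package: mitoribostall
Title: Mitoribosome Profiling Analysis of Polyproline Translational Stalling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Codon-resolution analysis of mitochondrial ribosome profiling
    data. Models the 13-ORF human mitochondrial transcriptome under the
    vertebrate mitochondrial genetic code, calibrates per-read-length 5' to
    A-site offsets from stop-codon metagene peaks refined by triplet
    phasing, builds per-codon occupancy profiles with within-transcript and
    across-transcriptome normalisation, detects genotype-dependent
    translational stall events and rolling-window polyproline occupancy
    ratios, and censuses proline runs, PP-containing triplets and pausing
    categories across mtDNA-encoded proteomes. A deterministic footprint
    simulator with known dwell-time structure provides ground truth for
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
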