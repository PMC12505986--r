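Package: statorevo
Title: Evolutionary and Structural Analysis of Bacterial Flagellar Stator Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolution of the MotAB/PomAB family of
    bacterial stator complexes and their non-flagellar homologs (ExbBD,
    TolQR and relatives). Provides synteny-based pairing of A-subunit
    homolog hits with their downstream B-subunit genes; alignment
    statistics including mean pairwise identity, per-column conservation,
    plug+linker region extraction and composition, and a permutation test
    for group differences; conditional clade distribution (CCD)
    summarization of Bayesian tree posteriors with clade-support entropy
    in natural log units, MAP summary trees and node-support annotation;
    marginal ancestral state reconstruction by Felsenstein pruning with
    presence-absence gap reconstruction and branch-length optimization;
    automated four-letter structural architecture classification of
    A-subunit monomer models from C-alpha geometry; and synthetic-data
    generators with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    bio3d,
    rtracklayer,
    GenomicRanges,
    IRanges,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
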