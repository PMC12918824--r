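Package: meiodel
Title: Simulation and Detection of Microdeletions at Meiotic DSB Hotspots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying mutagenic end joining at meiotic double-strand
    break (DSB) hotspots. Provides signal-processing primitives for SPO11-oligo
    coverage maps (Hann smoothing, local normalization, flip-and-average
    profile building), a synthetic-data generator that emulates SPO11 double
    cutting, end-joining junction formation (NHEJ and microhomology-mediated
    repair), ectopic and inverted insertions, nested-PCR well assays and
    amplicon paired-end sequencing, an amplicon split-read caller that merges
    read pairs, aligns them with a built-in affine-gap aligner, extracts
    deletion junctions from alignment operations, filters balanced-indel
    artifacts, infers junction microhomology or inserted bases and collapses
    PCR duplicates by alignment path, and the statistics used to compare
    end-joining breakpoint spectra across genotypes (chance-microhomology
    model, exact contingency tests, spread and shift tests, size
    stratification, strength-adjusted assay frequencies).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
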