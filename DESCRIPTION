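Package: SDRtools
Title: Sex-Determining Region Detection and X-Y Divergence Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for plant sex chromosomes built around pooled-depth
    delineation of the male-specific sex-determining region (SDR). Calls the
    SDR from female/male pool depth ratios, builds the X/Y gametolog catalogue
    by reciprocal best hit and quantifies Y gene loss, estimates synonymous
    divergence (Ks) by Nei-Gojobori counting with Jukes-Cantor correction and
    dates X-Y separation with a molecular clock, detects inverted anchor runs
    and breakpoints from gametolog synteny, and computes population statistics
    (variant classes, nucleotide diversity, Tajima's D, Hudson's FST) that
    contrast X- and Y-referenced call sets. Includes a seeded simulator that
    generates every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Rsamtools,
    rtracklayer,
    vcfR,
    data.table,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
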