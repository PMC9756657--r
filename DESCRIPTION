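Package: introscan
Title: Detecting Interspecific Introgression from Long Reads, Window
    Topologies and Allele Frequencies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects donor-genome introgression blocks in a focal fish
    assembly using three complementary lines of evidence: HiFi-style long
    reads that align fully to the focal assembly but split cleanly between
    two donor references; exhaustive topology weighting of
    neighbour-joining trees inferred in sliding windows; and
    allele-frequency admixture statistics (Patterson's D, f4-admixture
    ratio, f-branch) with block-jackknife significance. Also anchors
    assembly scaffolds into linkage groups from SNP-array probe hits and a
    genetic map, breaking chimeric scaffolds and emitting Marey-map QC
    tables. A synthetic-data module generates genomes with planted
    introgression tracts, reads, split alignments, genotypes and map
    fixtures with known truth, so every stage is verifiable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
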