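Package: missedgene
Title: Distinguishing Missed from Missing Genes in Draft Genome Assemblies
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An evidence chain for deciding whether a gene absent from a
    genome annotation is truly missing from the organism or merely missed
    because of assembly quality, modelled on the avian foxp3 case. Provides
    synteny-based locus classification from gene-neighbourhood annotations,
    assembly and region quality forensics (N50, GC content, repeat masking,
    gap runs), a spliced protein-to-genome aligner for exon recovery across
    gapped regions, FoxP-style domain architecture and clade signature-residue
    analysis, exact-match transcript-read coverage and in-silico PCR checks,
    and a rule-based integration of all evidence into a missed-versus-missing
    verdict. A synthetic-neighbourhood simulator with known ground truth and a
    GC-linked fragmentation model makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    GenomicRanges,
    IRanges,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
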