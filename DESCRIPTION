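Package: koalamhc
Title: High-Throughput MHC Immunogenetic Typing for Koalas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Amplicon-based genotyping of koala (Phascolarctos cinereus)
    major histocompatibility complex class I (UA, UC) and class II (DAB,
    DBB, DCB, DMB) genes from multiplexed paired-end Illumina reads.
    Implements primer-based locus assignment, primer trimming with a 150 bp
    length cull, overlap merging of read pairs, reference-database allele
    matching with a strict greater-than-10 percent read-fraction calling
    rule, novel-allele discovery from highly duplicated unmatched
    sequences, Mendelian congruence checking of dam-sire-joey family units
    with discrepancy classification, Gower/complete-linkage haplotype
    clustering, Fisher exact allele-phenotype association testing, and a
    ground-truth simulator of pedigrees and error-bearing amplicon reads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    cluster,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo: Rcpp
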