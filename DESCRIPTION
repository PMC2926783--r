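Package: lincons
Title: Comparative Conservation Analysis of Long Intergenic Noncoding RNA Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for the comparative-genomics
    characterisation of long intergenic noncoding RNA (lincRNA) loci:
    selection filters against protein-coding annotation (exonic overlap and
    a <5 kb proximity rule), overlap statistics against phastCons-style
    conserved elements, a generic-locus ("metagene") conservation profile
    with promoter-peak calling, evolutionarily conserved region (ECR)
    detection from pairwise alignments, BLASTn-style ortholog percent
    identity summaries, longest-ORF and Nei-Gojobori dN/dS coding-potential
    screening, and poly(A)/splice-site motif annotation. Includes readers
    and writers for BED6/BED12, bedGraph, MAF and FASTA, and a seeded
    synthetic-data generator that emulates the statistical structure of the
    real inputs so that every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
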