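Package: EmbryoPGT
Title: Embryo-as-Proband Haplotype Phasing and CNV Screening for PGT-M
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Preimplantation genetic testing for monogenic disease (PGT-M)
    when no family proband is available: an affected or carrier embryo serves
    as the proband to anchor which parental haplotype carries a pathogenic
    variant. Informative SNPs in a window around the variant are phased by a
    hidden Markov model with recombination-fraction transitions derived from a
    genetic map and an allele-dropout-aware emission model; sibling embryos
    are diagnosed by Viterbi decoding of their inherited parental haplotypes,
    reconciled with direct mutation tests. A companion module calls
    chromosomal copy-number variants from low-pass sequencing read depth
    (sliding-window binning, LOESS GC normalization, reference-panel log2
    ratios and Z-scores, circular binary segmentation) and gates haplotyping
    on embryo ploidy. A seeded simulator generates families, genotypes and
    depth profiles with the statistical structure the method assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    vcfR,
    rtracklayer,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
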