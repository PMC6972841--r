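Package: mirecip
Title: Small RNA Quantification, Differential Expression, and Reciprocal
    miRNA-mRNA Target Integration
Version: 0.1.0
Authors@R:
    person("mirecip", "maintainers", email = "mirecip@example.org",
           role = c("aut", "cre"))
Description: An integrated miRNA-seq/mRNA-seq analysis toolkit for
    two-group tissue designs. Implements adapter trimming with a
    minimum-overlap rule, 15-27 nt length filtering, exact (no-mismatch)
    alignment to a mature-miRNA reference, a +/-5 nt 5'-window counting
    rule with multi-locus collapsing and equal apportionment of
    multi-miRNA reads, RPM/presence filtering and mappable-read QC gates;
    negative-binomial Wald differential expression with Cox-Reid adjusted
    dispersion estimation and RUVg-style removal of unwanted variation;
    TargetScan-style seed-site scanning (8mer, 7mer-m8, 7mer-A1) of
    3'-UTRs; reciprocal-expression integration of inversely expressed
    miRNA-mRNA pairs; 2^-ddCt relative quantification for RT-qPCR; and a
    synthetic-data generator that produces reads, count matrices, and
    planted seed sites with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
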