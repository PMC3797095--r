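Package: aestimir
Title: Small RNA-Seq miRNA Profiling for Two-Library Comparisons
Version: 1.0.0
Authors@R:
    person("Aestimir", "Developers", email = "aestimir@example.org",
           role = c("aut", "cre"))
Description: An end-to-end small RNA sequencing analysis toolkit for two-library
    (pooled, replicate-free) miRNA studies, built around the digital expression
    statistics used for marine invertebrate aestivation profiling: adapter
    trimming and read cleaning, exact-match annotation against miRBase-style
    references, per-family temporary miRNA database construction, novel miRNA
    hairpin calling with a self-contained single stem-loop folding model,
    Audic-Claverie two-library differential expression with reads-per-million
    normalization and Benjamini-Hochberg FDR, TargetScan-style seed-site
    prediction (8mer, 7mer-m8, 7mer-1a), GO term over-representation, stem-loop
    RT-qPCR 2^-ddCt quantification, and a fully synthetic data generator with
    ground-truth tables for validation without any external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
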