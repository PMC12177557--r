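Package: bloodeqtl
Title: Mixed-Model eQTL Discovery, Hotspot Detection and Colocalization for Blood Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end expression quantitative trait locus (eQTL) discovery
    chain for bulk RNA-seq expression measured alongside dense genotypes:
    TMM normalization and expression-level filtering, variant quality control
    and linkage-disequilibrium pruning to count independent tests, genomic
    relationship matrix (GRM) based linear mixed-model association scans with
    a Bonferroni threshold on independent SNPs, eQTL region calling with
    cis/trans classification, trans-regulatory hotspot detection, overlap of
    health-trait QTLs with cis-eQTLs, approximate-Bayes-factor colocalization
    with 95 percent credible sets, and partial-correlation (PCIT)
    co-expression networks. Includes a synthetic-data module that simulates
    LD-structured genotypes, negative-binomial counts with planted cis and
    trans-hotspot effects, and quantitative traits sharing causal variants
    with gene expression, so every stage can be validated against a known
    regulatory architecture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    edgeR,
    IRanges,
    S4Vectors,
    vcfR,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
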