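Package: methtopo
Title: Functional and Topographic DNA Methylation Analysis for IDH-Mutant Cancers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for Illumina 450K/EPIC methylation array data
    from IDH1/2-mutant tumors: detection p-value sample QC, sex-probe removal,
    cross-platform probe harmonization, quantile normalization, beta/M-value
    conversion, mean-M hyper/hypomethylation state calling at the +/-2 cutoff,
    per-probe Welch differential methylation with Benjamini-Hochberg FDR,
    cross-tumor common/unique probe-set algebra and specificity summaries,
    functional-region (promoter/gene body/enhancer) partitioning,
    coverage-normalized per-chromosome-arm methylation ratios with bootstrap
    arm-versus-genome tests, methylation-desert cytoband detection, bedGraph
    track export, and hypergeometric over-representation analysis. A seeded
    synthetic array-data generator with planted functional and topographic
    effects drives end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    fgsea,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
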