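Package: cismeth
Title: Mapping and Interpreting Cis Methylation QTLs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An analysis toolkit for cis methylation QTL (meQTL) studies on
    array methylation data with matched genotypes. Implements two-stage
    rank-based quantile normalization of beta values, principal-component
    confounder removal with data-driven selection of the number of
    components, a windowed cis association scan with Storey q-value FDR
    control, lead-SNP calling, a candidate-causal SNP filter based on
    p-value gaps, matched-SNP permutation tests for cross-phenotype QTL
    sharing, chromatin-annotation enrichment, genotype-stratified
    aggregation of low-coverage bisulfite sequencing reads around meQTLs,
    and tests linking predicted transcription-factor binding affinity to
    nearby methylation. A synthetic-data module generates genotypes with
    LD structure, bimodal methylation with planted cis effects and hidden
    confounders, binomial bisulfite reads, linked phenotypes, and motif
    fixtures, so every stage of the pipeline can be validated against
    known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
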