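Package: eqtlnet
Title: Bipartite eQTL Networks with FDR-Based Edge Definitions and Degree Stability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs bipartite SNP-gene networks from expression quantitative
    trait locus (eQTL) association scans and evaluates competing edge and degree
    definitions. Provides exhaustive covariate-adjusted linear-model eQTL mapping
    with cis/trans classification; four edge-significance measures (Storey
    q-value, local false discovery rate, a streamed top-K adaptation of
    Benjamini-Hochberg, and the non-null-proportion degree); sparse unweighted
    and |Z|-weighted adjacency construction with degree decomposition;
    split-sample and cross-network degree reproducibility protocols with
    random-effects meta-analysis of Spearman correlations; per-gene nucleotide
    diversity and Tajima's D; and stratified LD-score regression for heritability
    enrichment of degree-derived annotations. A synthetic-data module generates
    genotypes, expression with planted eQTL architecture, neutral coalescent
    haplotypes, and model-consistent GWAS chi-square statistics so the whole
    pipeline is testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    splines,
    metafor,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
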