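# eqtlnet

Bipartite eQTL networks with FDR-based edge definitions, degree-centrality
stability evaluation, and downstream population-genetic and heritability
analyses.

## The problem

Expression quantitative trait locus (eQTL) mapping associates SNP genotypes
with gene expression. The full result of an exhaustive scan is naturally a
*bipartite network*: SNPs and genes are the two node classes, and a function
of each pairwise association defines the edges. Most published eQTL networks
dichotomize associations at a fixed FDR cutoff, but the choice of
significance measure, threshold, and weighting changes the network — and with
it the *degree* of each node, the centrality statistic used to nominate
influential regulatory SNPs and highly regulated genes. `eqtlnet` implements
the competing network specifications and the protocols for deciding between
them, for statistical geneticists who want degree estimates they can trust.

## The model

For sample-by-SNP dosages `S` and sample-by-gene expression `G` with
covariates `X`, every pair (i, j) is scored by the linear model

    G_j = X' alpha + beta_ij S_i + e,

with Wald statistic `z_ij = beta_ij / SE(beta_ij)` and two-sided p-value.
Pairs within 1 Mb of the gene's transcription start site are *cis*; all
others are *trans*. Sparse adjacencies set

    a_ij = |z_ij| * I{ Y_ij < tau },    tau in {0.05, 0.1, 0.15, 0.2},

where the significance measure `Y` is a Storey q-value (QV), a local FDR
(LFDR), or a streamed top-K adaptation of Benjamini-Hochberg (BH) that needs
only the K smallest of N p-values:

    q_K = (N/K) p_K,    q_i = min((N/i) p_i, q_{i+1}).

Degree is the sum of incident edge weights, decomposed into cis and trans
components. A denser representation keeps every p-value and defines the
non-null-proportion (NP) degree of a node as `1 - pi0(its p-values)`.

Around this core, the package provides:

- **Stability protocols** — split-sample Spearman correlation of degree
  (five random half-splits, full pipeline per half), cross-network degree
  correlation, and DerSimonian–Laird random-effects meta-analysis of
  correlations on the Fisher-z scale.
- **Genetic diversity** — per-gene nucleotide diversity and Tajima's D from
  haplotype alignments, correlated with gene degree across datasets.
- **Heritability enrichment** — stratified LD-score regression
  `E[chi^2_j] = N * sum_c l(j,c) tau_c + 1` with block-jackknife errors,
  standardized effect sizes `tau*`, and enrichment of degree-derived
  SNP annotations (binary top-quartile, or continuous gene-window).
- **Synthetic data** — Hardy–Weinberg genotypes, expression with a planted
  cis/trans eQTL architecture, neutral coalescent haplotypes, and GWAS
  chi-square statistics drawn from the LD-score model, so the whole pipeline
  is testable without access-controlled data.

## Worked example

```r
library(eqtlnet)

geno  <- simulate_genotypes(n_samples = 400, n_snps = 150, seed = 1)
genes <- simulate_genes(60, geno, seed = 2)
arch  <- plant_architecture(geno, genes, n_cis = 25, n_trans = 10,
                            beta_cis = 1, beta_trans = 0.6, seed = 3)
covs  <- simulate_covariates(400, 3, seed = 4)
expr  <- simulate_expression(geno, arch, covs, seed = 5)

res <- map_eqtls(geno, expr, covs)
#> eqtl_result_set (dense storage): 9000 entries; 1032 cis + 7968 trans tests
#> over 150 SNPs x 60 genes

bh  <- edge_measures(res, kind = "BH")
net <- build_sparse_adjacency(res, bh, tau = 0.05, weighted = TRUE)
#> adjacency_view (sparse-weighted, tau=0.05, BH): 36 edges over 150 SNPs x 60 genes

deg <- degree_sparse(net, axis = "SNP")
#> degree_vector (SNP, BH, weighted): 150 nodes, degree range [0, 22.7443]

stab <- split_sample_stability(geno, expr, covs, definition = "BH",
                               tau = 0.05, weighted = TRUE, seed = 6)
#> split-sample stability (BH, tau=0.05, weighted, 5 repeats):
#>  axis stratum       rho
#>  gene     cis 0.9606583
#>   SNP     cis 0.9611573
#>  gene    full 0.9048845
#>   SNP    full 0.9019417
#>  gene   trans 0.4619303
#>   SNP   trans 0.4938046
```

Reading the output: of the 9,000 SNP–gene tests, 36 pairs survive the
BH-adapted FDR at `tau = 0.05` and form the sparse weighted network. Most of
the 150 SNPs therefore have degree 0, while the largest hub accumulates
|z|-weighted degree 22.7 — the right-skew expected of eQTL networks. The
split-sample protocol then shows that cis degree ranks are highly
reproducible across independent half-samples (Spearman rho about 0.96),
trans degree much less so (about 0.46–0.49): trans effects are weaker here
by construction, so their degree estimates are noisier — the same ordering
that motivates stratifying networks by location.

`run_pipeline(default_config(out_dir, seed))` runs every stage
(simulate → map → measures → network/degree → stability → diversity →
LD-score regression) into one run directory with a JSON manifest of
checksums; reruns under the same config are bit-identical.

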