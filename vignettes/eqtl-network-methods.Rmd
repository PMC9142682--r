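---
title: "Methods: bipartite eQTL networks, degree stability, and downstream analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bipartite eQTL networks, degree stability, and downstream analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqtlnet)
```

## Scope and assumptions

`eqtlnet` treats an exhaustive eQTL scan as a bipartite SNP–gene network and
asks how the network — and especially node degree — depends on how edges are
defined. The statistical model is deliberately simple and standard: for each
SNP `i` and gene `j`,

$$ G_j = X^\top\alpha + \beta_{ij} S_i + \varepsilon, $$

fit by OLS with an intercept and user-supplied covariates (genotype PCs,
sex, platform, latent expression factors — the package consumes them as
given and never estimates them). The Wald statistic is
$z_{ij} = \hat\beta_{ij}/\mathrm{SE}(\hat\beta_{ij})$. Assumptions: additive
dosage effects, Gaussian residuals (only relevant for small samples), shared
sample ordering across genotype/expression/covariate inputs, and covariates
of full rank with the intercept.

Computationally, `map_eqtls()` residualizes dosages and expression on the
covariates once and forms all cross-products in a single matrix product; the
Frisch–Waugh theorem guarantees this equals the per-pair joint fit, and a
test asserts agreement with `lm()` to 1e-8. SNPs that are constant after
projection are *untestable*: excluded from results and from the
multiple-testing denominators, and listed by id.

### Wald reference: normal vs t

Edge weights throughout are |z|, so the default p-value is two-sided normal,
keeping `p = 2*pnorm(-|z|)` exactly consistent with the weights. At the
sample sizes the method targets (hundreds of samples) the difference from
the exact t reference is negligible; `df_method = "t"` is exposed for small
samples, and the calibration tests use it.

### cis/trans classification

A pair is cis iff same chromosome and `|snp_pos - tss| <= window`, window
defaulting to 1 Mb. The boundary is *inclusive*; "within 1 Mb" is otherwise
ambiguous and any convention only moves single pairs at the boundary. Strand
is ignored; everything else (including all cross-chromosome pairs) is trans.

## Edge-significance measures

Four measures `Y` are available, each mapped to `[0, 1]`:

* **QV** — Storey q-values: running minimum of
  $\hat\pi_0 m p_{(i)} / i$ from the largest p downward.
* **LFDR** — local FDR $\pi_0 f_0(z)/f(z)$, with `f` estimated by Lindsey's
  method (histogram counts, Poisson log-linear fit in a natural-spline
  basis; 120 bins, 7 df by default) and `f0` standard normal by default.
  An empirical-null option recenters/rescales `f0` by the median and
  IQR/1.349 of `z` (central matching). Estimates are clamped to `[0, 1]`;
  an isotonic option additionally enforces nonincreasing lfdr in |z|.
* **BH** — a streamed adaptation of Benjamini–Hochberg that needs only the
  K smallest of N p-values: $q_K = (N/K)p_K$,
  $q_i = \min((N/i)p_i,\, q_{i+1})$. With K = N this is exactly the
  textbook step-up adjustment (asserted to 1e-12 against `p.adjust`).
  The raw recursion can exceed 1, so outputs are clamped — FDR semantics
  require it.
* **NP** — the non-null proportion $1-\hat\pi_0$ of a p-value set; not an
  edge measure but the degree definition for the dense representation.

### $\pi_0$ estimation

$\hat\pi_0(\lambda) = \#\{p > \lambda\}/(m(1-\lambda))$ on the grid
$\lambda = 0.05, 0.10, \dots, 0.95$, followed by a cubic smoothing spline
(3 df) extrapolated to $\lambda = 1$. When the smoother returns a
non-finite or non-positive value, the estimate at the largest grid point is
used instead; the result is floored at `1/m` and capped at 1. On the
mixture `0.8 U(0,1) + 0.2 Beta(0.1, 10)` at m = 10^4 the estimator recovers
$\pi_0$ within ±0.05 (tested for $\pi_0 \in \{0.5, 0.8, 1\}$).

### Scoping

QV and LFDR are computed per SNP (across that SNP's genes); BH is computed
globally per stratum using the exact recorded test counts as N. These are
the defaults because they match how the measures are used together: the
per-SNP measures need each node's complete statistic vector (hence dense
storage), while the streamed BH is exactly what makes threshold-level
storage possible. Per-gene and global scopes are exposed as options. In
location-specific mode (the default) cis and trans test sets are treated as
separate strata; genome-wide mode pools them. The same per-SNP measures are
reused for both degree axes rather than recomputed per gene — recomputation
is available via `scope = "per-gene"` but is not the default, since a single
measure per edge keeps the SNP- and gene-degree networks identical.

## Networks and degree

Sparse edges exist iff `Y < tau` — strictly, as the indicator is written, so
`Y = tau` is *not* an edge; weights are `|z|` (weighted) or 1. Thresholds
0.05–0.2 are conventional, any value in (0,1) is accepted. Degree is the sum
of incident weights with cis/trans parts tracked separately; nodes with no
edges have degree 0 and are retained. The dense representation stores every
p-value; the NP degree of a node is the non-null proportion of its incident
p-vector (floor: 10 tests per node), genome-wide only — a cis/trans split of
a per-node $\pi_0$ estimate would condition the estimator on tiny,
selection-biased p-vectors.

Annotations for heritability analysis: the binary top-quartile annotation
marks nodes with degree at or above the linear-interpolation 75th
percentile (binary for estimate stability); all-equal degrees trigger a
warning and a degenerate all-ones annotation. The continuous gene-window
annotation gives every SNP inside a gene span (or TSS point) ± 50 kb that
gene's degree, resolving overlaps by maximum — a deliberate choice where any
convention is defensible; the maximum preserves "is near a hub" semantics.
Note that at desk scale the sparse degree is mostly exactly zero, so its
top-quartile annotation can degenerate; the pipeline's demonstration stage
therefore annotates the continuous NP degree.

The signed-weight transform for regulatory-network edge weights,
$W = \ln(e^w + 1)$, is evaluated as `max(w,0) + log1p(exp(-|w|))` so
large |w| cannot overflow.

## Stability protocols

`split_sample_stability()` randomly splits samples into halves of size
⌈r/2⌉ and ⌊r/2⌋ (disjoint, exhaustive, re-randomized each of 5 repeats by
default), runs the full pipeline independently per half, and reports the
Spearman correlation between the halves' degree vectors per axis and
stratum. Spearman is used throughout because degree distributions are
right-skewed. Covariates are subset per half, not re-estimated. The node set
for each correlation is the nodes testable in *both* halves, including
zero-degree nodes (average ranks handle the ties); a nonzero-in-either rule
is exposed for cross-network comparisons.

Two degenerate regimes deserve note. Under a pure global null the sparse
network at `tau = 0.05` typically has no edges at all, both half degree
vectors are identically zero, and the correlation is undefined (`NaN`, with
a warning — the package's constant-vector convention). The null-behavior
checks therefore use the NP degree, which is continuous and defined for
every node, and whose split correlation concentrates near zero as expected.

Correlations are pooled across datasets with a random-effects meta-analysis:
Fisher z-transform with variance `1/(n-3)`, DerSimonian–Laird between-study
variance, inverse-variance pooling, and `tanh` back-transform of estimate
and 95% CI. The computation is delegated to `metafor::rma(method = "DL")`;
the test suite checks it against an independently hand-coded DL oracle to
1e-10. Correlations of exactly ±1 have infinite Fisher z and are clamped
just inside the boundary (at 1 − 1e-10) so pooling stays finite.

## Population genetics

`simulate_haplotypes()` is a Kingman coalescent under infinite sites with no
recombination: exponential waiting times with rate `k(k-1)/2`, mutations
Poisson with rate θ/2 per unit branch length. This is sufficient for its
purpose — a neutral substrate on which E[S] = θ·a₁ and E[π·L] = θ hold and
Tajima's D centers near zero — and deliberately nothing more.

Per-site diversity uses folded counts,
$\pi = \sum_s 2 j_s (h - j_s)/(h(h-1)) / L$, which equals the mean pairwise
difference (asserted to 1e-12 against explicit pair enumeration) and is
invariant to ancestral/derived relabeling. Monomorphic positions contribute
0 but count in L. Tajima's D uses the standard 1989 constants, computed in
`tajima_constants()` and verified against an independently coded oracle;
S = 0 leaves D as `NaN` with the segregating-site count reported. Under the
neutral simulation at n = 20, θ = 5 over 2000 replicates the mean of π·L is
within 5% of θ and mean D within ±0.1 of 0 (D has the well-known small
negative finite-sample mean).

## Heritability enrichment

LD scores are $l(j,c) = \sum_k a_{ck} r^2_{jk}$ with unadjusted squared
Pearson correlations between dosage vectors within a 1 Mb window (a proxy
for the conventional 1 cM) and the self term always included; with no LD the
score reduces to the annotation itself. The regression
$E[\chi^2_j] = N \sum_c l(j,c)\tau_c + 1$ is fit by unweighted least squares
with the intercept *fixed at 1* by default — the model's "+1" is the null
expectation — with a free-intercept option for confounding scenarios (note a
free intercept is collinear with an all-ones base annotation, and the fit
says so). Standard errors, p-values, and enrichment uncertainty come from a
leave-one-block-out jackknife over contiguous SNP blocks, default 20 blocks
at desk scale (reference-scale analyses conventionally use 200; the count is
configurable). Enrichment is
$[h^2(C)/h^2_g] / [\sum_j a_{jc}/M]$ with $\mathrm{Var}(\beta_j) = \sum_c
a_{cj}\tau_c$; the all-ones annotation has enrichment identically 1, and
$\tau^*_c = \tau_c\,\mathrm{sd}(c)/(h^2_g/M)$ standardizes effects per SD of
annotation.

The χ² simulator draws independent 1-df noncentral χ² variables whose means
follow the same linear model; LD enters only through the mean. That is
exactly the regression being tested, which is the point: it isolates the
estimator's behavior (exact recovery on noiseless input at machine
precision; <10% relative bias and ≥90% jackknife CI coverage on stochastic
input) from LD-panel quality, which is out of scope.

## The synthetic-data generator

The generator defines the study conditions for every test:

* **Genotypes** — hard-call dosages as sums of two Bernoulli(maf) alleles
  (Hardy–Weinberg), MAF uniform on [0.05, 0.5] by default (the 0.05 floor
  mirrors standard QC), SNPs on two chromosomes at 100 kb spacing.
  Hard calls keep the Hardy–Weinberg checks exact; continuous dosages are
  accepted on input but not generated.
* **Architecture** — planted cis edges are drawn among pairs within the 1 Mb
  window; planted trans edges strictly across chromosomes, so labels are
  unambiguous. Defaults: 35 cis + 15 trans edges, β = 1, residual sd 1 —
  chosen once as a strong-but-not-saturated signal at n of a few hundred
  (per-edge |z| around 8–12), the regime where stability comparisons are
  informative. Where a weaker trans architecture is wanted (the cis-vs-trans
  stability comparison), trans β = 0.5–0.6 is used and stated.
* **Expression** — planted effects + covariate effects + Gaussian noise;
  with no planted edges, downstream p-values are uniform (KS-tested).
* **GWAS** — the χ² model above, N = 10^4 and τ around 10^-4 so mean χ² ≈ 2.

What it does **not** emulate: linkage disequilibrium and recombination maps,
population structure, expression normalization pipelines (TMM,
inverse-normal — values are emitted already normalized), realistic
PEER-style latent structure (covariates are generic Gaussians), and
selection or demography in the coalescent. Passing tests therefore
demonstrate correctness of the estimators and protocols under clean
conditions, not robustness to the correlated noise of real cohorts.

## Problem sizes and determinism

The test and acceptance workloads use up to 800 samples, 150–300 SNPs,
60–120 genes (36,000 pairwise tests), 24,000-test p-vectors for NP
calibration, 2000 coalescent replicates, and 50-seed LD-score simulations at
10^4 SNPs — sizes chosen so the full suite completes in minutes on one CPU
while keeping Monte-Carlo error well inside each tolerance. Every stochastic
function takes an explicit seed, restores the caller's RNG state, and
derives child seeds arithmetically (kept below 2^31), so any run —
including the full pipeline with its manifest of MD5 checksums — is
bit-reproducible from a single integer.

## Known limitations

* Exhaustive dense mapping stores n×m entries in memory; the streamed mode
  bounds storage (all cis plus trans with p ≤ 1e-3 by default) but QV/LFDR
  then cannot be computed, exactly because their per-node p-vectors are
  incomplete.
* The LFDR density fit needs a few hundred statistics to be stable; per-SNP
  scoping at small gene counts is allowed but noisy, and sparse tail bins
  can trip (suppressed) GLM convergence warnings.
* The LD-score window is a flat bp window, not genetic distance; r² is not
  bias-corrected.
* Meta-analysis assumes independent studies; overlapping-sample designs are
  not modeled.
* External-input mode of the pipeline runner (mapping user-supplied files
  end to end) is limited to the individual stage functions; `run_pipeline()`
  currently requires the simulation stage.
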