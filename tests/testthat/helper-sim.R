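# Shared simulation fixtures, built in code at test time.

# One synthetic dataset: genotypes, genes, planted architecture, covariates,
# expression. All sub-seeds derive from `seed`.
make_sim <- function(n_samples = 300L, n_snps = 200L, n_genes = 80L,
                     n_cis = 35L, n_trans = 15L,
                     beta_cis = 1, beta_trans = 1, noise_sd = 1,
                     n_cov = 3L, seed = 1L) {
  geno <- simulate_genotypes(n_samples, n_snps, seed = seed)
  genes <- simulate_genes(n_genes, geno, seed = seed + 1L)
  arch <- plant_architecture(geno, genes, n_cis = n_cis, n_trans = n_trans,
                             beta_cis = beta_cis, beta_trans = beta_trans,
                             noise_sd = noise_sd, seed = seed + 2L)
  X <- simulate_covariates(n_samples, n_cov, seed = seed + 3L)
  expr <- simulate_expression(geno, arch, X, seed = seed + 4L)
  list(geno = geno, genes = genes, arch = arch, X = X, expr = expr)
}

# Hand-built eqtl_result_set for adjacency/degree unit tests.
fake_results <- function(entries, snp_ids = unique(entries$snp_id),
                         gene_ids = unique(entries$gene_id),
                         store = "dense") {
  structure(
    list(entries = entries,
         n_tests_cis = sum(entries$cis), n_tests_trans = sum(!entries$cis),
         store = store, snp_ids = snp_ids, gene_ids = gene_ids,
         untestable = character(0)),
    class = "eqtl_result_set"
  )
}

fake_measures <- function(y, kind = "QV") {
  structure(list(measure = y, kind = kind, scope = "per-snp",
                 strata = "location-specific"),
            class = "significance_table")
}
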