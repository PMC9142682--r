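test_that("Spearman correlation is rank-invariant and matches the rank-Pearson oracle", {
  x <- c(-2, -1, 0.5, 1, 3)
  expect_equal(spearman_rho(x, x^3), 1)
  expect_equal(spearman_rho(x, -x), -1)
  set.seed(21)
  xt <- sample(rep(1:4, 5)); yt <- sample(rep(1:5, 4))  # heavy ties
  oracle <- stats::cor(rank(xt), rank(yt))
  expect_equal(spearman_rho(xt, yt), oracle, tolerance = 1e-12)
  expect_warning(r <- spearman_rho(rep(1, 5), 1:5), "constant")
  expect_true(is.nan(r))
  expect_error(spearman_rho(1:3, 1:4), "equal length")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("median/IQR summaries use linear-interpolation quantiles", {
  expect_equal(summarize_median_iqr(c(1, 2, 3, 4)),
               c(median = 2.5, iqr = 1.5))
  expect_equal(summarize_median_iqr(7), c(median = 7, iqr = 0))
  set.seed(22)
  v <- rnorm(31)
  expect_equal(summarize_median_iqr(v), summarize_median_iqr(sample(v)))
  expect_error(summarize_median_iqr(numeric(0)), "empty")
})

test_that("split halves are disjoint, exhaustive, near-equal, and seed-stable", {
  sim <- make_sim(n_samples = 101, n_snps = 60, n_genes = 30,
                  n_cis = 10, n_trans = 5, seed = 131)
  rep1 <- split_sample_stability(sim$geno, sim$expr, sim$X,
                                 n_repeats = 3, seed = 77)
  rep2 <- split_sample_stability(sim$geno, sim$expr, sim$X,
                                 n_repeats = 3, seed = 77)
  expect_identical(rep1$detail, rep2$detail)
  expect_identical(nrow(rep1$detail), 3L * 2L * 3L)  # repeats x axes x strata
  expect_true(all(rep1$detail$rho >= -1 & rep1$detail$rho <= 1, na.rm = TRUE))
  # odd sample count: ceiling/floor halves differing by one
  splits <- with(list(r = 101), {
    set.seed(77); lapply(1:3, function(k) sample.int(r, ceiling(r / 2)))
  })
  expect_true(all(lengths(splits) == 51L))
  tiny <- make_sim(n_samples = 5, n_snps = 10, n_genes = 5,
                   n_cis = 1, n_trans = 1, n_cov = 0, seed = 1)
  expect_error(split_sample_stability(tiny$geno, tiny$expr, NULL), "at least 6")
})

test_that("cross-network correlation respects the shared-node inclusion rule", {
  mk_deg <- function(ids, vals) {
    structure(list(table = data.frame(node_id = ids, total = vals,
                                      cis_part = 0, trans_part = 0),
                   axis = "SNP", weighted = TRUE, definition = "BH"),
              class = "degree_vector")
  }
  ids <- sprintf("s%05d", 1:1e4)
  set.seed(23)
  a <- mk_deg(ids, rexp(1e4))
  expect_equal(cross_network_correlation(a, a)$rho, 1)
  b <- mk_deg(ids, rexp(1e4))
  out <- cross_network_correlation(a, b)
  expect_lt(abs(out$rho), 0.03)
  expect_identical(out$n, 10000L)
  # nonzero rule restricts the node set
  c1 <- mk_deg(letters[1:6], c(0, 0, 1, 2, 3, 4))
  c2 <- mk_deg(letters[1:6], c(0, 0, 2, 1, 4, 3))
  expect_identical(cross_network_correlation(c1, c2, inclusion = "nonzero")$n, 4L)
  expect_error(cross_network_correlation(c1, mk_deg(LETTERS[1:5], 1:5)),
               "no shared nodes")
})

test_that("two datasets sharing a planted cis architecture have correlated SNP degrees", {
  geno1 <- simulate_genotypes(250, 100, seed = 141)
  geno2 <- simulate_genotypes(250, 100, seed = 142)
  genes <- simulate_genes(40, geno1, seed = 143)
  arch <- plant_architecture(geno1, genes, n_cis = 20, n_trans = 5, seed = 144)
  deg_of <- function(geno, expr_seed) {
    expr <- simulate_expression(geno, arch, seed = expr_seed)
    res <- map_eqtls(geno, expr)
    y <- edge_measures(res, kind = "BH")
    degree_sparse(build_sparse_adjacency(res, y, tau = 0.05), "SNP")
  }
  d1 <- deg_of(geno1, 145)
  d2 <- deg_of(geno2, 146)
  out <- cross_network_correlation(d1, d2)
  expect_gt(out$rho, 0)
  ct <- stats::cor.test(rank(d1$table$total), rank(d2$table$total),
                        alternative = "greater")
  expect_lt(ct$p.value, 0.01)
})

test_that("DerSimonian-Laird pooling matches the hand-coded formula oracle", {
  # oracle: independent implementation of Fisher-z DL
  dl_oracle <- function(rho, n) {
    z <- atanh(rho); v <- 1 / (n - 3); w <- 1 / v
    zbar <- sum(w * z) / sum(w)
    q <- sum(w * (z - zbar)^2)
    tau2 <- max(0, (q - (length(z) - 1)) / (sum(w) - sum(w^2) / sum(w)))
    ws <- 1 / (v + tau2)
    mu <- sum(ws * z) / sum(ws)
    se <- sqrt(1 / sum(ws))
    list(pooled = tanh(mu), tau2 = tau2,
         ci = tanh(mu + c(-1, 1) * stats::qnorm(0.975) * se))
  }
  fit <- random_effects_meta(c(0.2, 0.4), c(103, 203))
  ora <- dl_oracle(c(0.2, 0.4), c(103, 203))
  expect_equal(fit$pooled, ora$pooled, tolerance = 1e-10)
  expect_equal(fit$tau2, ora$tau2, tolerance = 1e-10)
  expect_equal(c(fit$ci_lower, fit$ci_upper), ora$ci, tolerance = 1e-10)

  set.seed(24)
  for (k in 1:5) {
    rho <- runif(4, -0.5, 0.7); n <- sample(20:300, 4)
    fit <- random_effects_meta(rho, n)
    ora <- dl_oracle(rho, n)
    expect_equal(fit$pooled, ora$pooled, tolerance = 1e-10)
    expect_equal(fit$tau2, ora$tau2, tolerance = 1e-10)
    expect_true(fit$pooled >= min(rho) - 1e-12 && fit$pooled <= max(rho) + 1e-12)
    expect_true(fit$ci_lower <= fit$pooled && fit$pooled <= fit$ci_upper)
  }
})

test_that("homogeneous correlations pool to the common value with zero heterogeneity", {
  fit <- random_effects_meta(rep(0.3, 4), c(50, 80, 120, 200))
  expect_equal(fit$pooled, 0.3, tolerance = 1e-12)
  expect_equal(fit$tau2, 0)
  expect_error(random_effects_meta(0.3, 50), "at least 2")
  expect_error(random_effects_meta(c(0.1, 0.2), c(3, 50)), "n > 3")
})
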