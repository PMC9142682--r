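hap_of <- function(mat, L) {
  list(haplotypes = mat, locus_length = L)
}

test_that("per-site diversity matches its closed forms and the pairwise oracle", {
  # 2 haplotypes differing at 1 of 10 sites
  h2 <- hap_of(matrix(c(0, 1), nrow = 2, ncol = 1), 10)
  expect_equal(nucleotide_diversity(h2), 0.1)
  # 4 haplotypes, one site with derived count 1, length 100
  h4 <- hap_of(matrix(c(1, 0, 0, 0), nrow = 4, ncol = 1), 100)
  expect_equal(nucleotide_diversity(h4), 2 * 1 * 3 / (4 * 3) / 100)

  # brute-force mean pairwise difference over all C(h,2) pairs
  pairwise_oracle <- function(hap) {
    m <- hap$haplotypes
    h <- nrow(m)
    tot <- 0
    for (i in seq_len(h - 1)) {
      for (j in seq(i + 1, h)) tot <- tot + sum(m[i, ] != m[j, ])
    }
    tot / choose(h, 2) / hap$locus_length
  }
  set.seed(31)
  for (k in 1:5) {
    hap <- hap_of(matrix(rbinom(7 * 12, 1, 0.4), nrow = 7), 50)
    expect_equal(nucleotide_diversity(hap), pairwise_oracle(hap), tolerance = 1e-12)
  }
})

test_that("Tajima's D matches an independently coded constants oracle", {
  # oracle: recompute every constant from scratch with different algebra
  tajima_oracle <- function(mat) {
    n <- nrow(mat); s <- ncol(mat)
    if (s == 0) return(NaN)
    a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
    # mean pairwise difference by explicit enumeration
    k_sum <- 0; n_pair <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      k_sum <- k_sum + sum(mat[i, ] != mat[j, ]); n_pair <- n_pair + 1
    }
    k_bar <- k_sum / n_pair
    b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    (k_bar - s / a1) / sqrt(c1 / a1 * s + c2 / (a1^2 + a2) * s * (s - 1))
  }
  fixture <- matrix(c(0, 1, 1, 0, 0, 1,
                      1, 1, 0, 0, 1, 0,
                      0, 0, 1, 1, 0, 0,
                      0, 1, 0, 1, 0, 1,
                      1, 0, 0, 0, 1, 1,
                      0, 1, 1, 0, 1, 0,
                      1, 0, 1, 1, 0, 0,
                      0, 0, 0, 1, 1, 1), nrow = 6, ncol = 8)
  expect_equal(tajimas_d(hap_of(fixture, 100))$d, tajima_oracle(fixture),
               tolerance = 1e-10)
  set.seed(32)
  for (k in 1:5) {
    mat <- matrix(rbinom(9 * 15, 1, 0.3), nrow = 9)
    mat <- mat[, colSums(mat) > 0 & colSums(mat) < 9, drop = FALSE]
    expect_equal(tajimas_d(hap_of(mat, 10))$d, tajima_oracle(mat), tolerance = 1e-10)
  }
})

test_that("Tajima's D is undefined at S = 0 and invariant to allele relabeling", {
  empty <- hap_of(matrix(0L, 5, 0), 100)
  out <- tajimas_d(empty)
  expect_true(is.nan(out$d))
  expect_identical(out$n_segregating, 0L)
  set.seed(33)
  mat <- matrix(rbinom(8 * 10, 1, 0.5), nrow = 8)
  expect_equal(tajimas_d(hap_of(mat, 10))$d, tajimas_d(hap_of(1L - mat, 10))$d,
               tolerance = 1e-12)
  expect_equal(nucleotide_diversity(hap_of(mat, 10)),
               nucleotide_diversity(hap_of(1L - mat, 10)), tolerance = 1e-12)
})

test_that("per-gene diversity tables flag undefined D and propagate gene ids", {
  haps <- list(gA = simulate_haplotypes(10, 3, seed = 34),
               gB = hap_of(matrix(0L, 5, 0), 100))
  tab <- diversity_table(haps)
  expect_identical(tab$gene_id, c("gA", "gB"))
  expect_true(is.nan(tab$tajima_d[2]) && tab$n_segregating[2] == 0)
  expect_true(all(tab$pi >= 0))
})

test_that("degree-diversity correlation finds planted dependence and respects the null", {
  mk_deg <- function(ids, vals) {
    structure(list(table = data.frame(node_id = ids, total = vals,
                                      cis_part = 0, trans_part = 0),
                   axis = "gene", weighted = TRUE, definition = "BH"),
              class = "degree_vector")
  }
  ids <- sprintf("g%03d", 1:60)
  set.seed(35)
  deg <- lapply(1:3, function(k) mk_deg(ids, rexp(60)))
  names(deg) <- paste0("tissue", 1:3)

  # diversity identical to degree ranks -> pooled rho = 1
  div1 <- data.frame(gene_id = ids, pi = rank(deg[[1]]$table$total))
  one <- correlate_degree_diversity(deg[1:2], div1, "pi")
  # dataset 2 has independent degrees, so restrict the perfect check to dataset 1
  expect_equal(one$per_dataset$rho[1], 1)

  # planted monotone dependence with noise: pooled rho > 0, CI excludes 0
  shared <- rexp(60)
  deg2 <- lapply(1:3, function(k) mk_deg(ids, shared + rnorm(60, sd = 0.1)))
  div2 <- data.frame(gene_id = ids, pi = qexp(pmin(0.999, pmax(0.001,
                     pnorm(scale(shared) + rnorm(60, sd = 0.5))))))
  sig <- correlate_degree_diversity(deg2, div2, "pi")
  expect_gt(sig$meta$pooled, 0)
  expect_gt(sig$meta$ci_lower, 0)

  # independent simulations: pooled CI covers 0 in >= 90% of 50 runs
  covered <- vapply(1:50, function(r) {
    set.seed(400 + r)
    d <- lapply(1:2, function(k) mk_deg(ids, rexp(60)))
    dv <- data.frame(gene_id = ids, pi = rexp(60))
    m <- correlate_degree_diversity(d, dv, "pi")$meta
    m$ci_lower <= 0 && 0 <= m$ci_upper
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})
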