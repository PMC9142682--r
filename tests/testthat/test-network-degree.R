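tiny_entries <- function() {
  data.frame(
    snp_id = rep(c("s1", "s2", "s3"), each = 2),
    gene_id = rep(c("g1", "g2"), 3),
    beta = c(0.5, -0.4, 0.1, 0.9, -0.2, 0.3),
    z = c(-3.2, 2.0, 0.5, 4.1, -1.0, 1.5),
    p = c(0.0014, 0.0455, 0.6171, 4.1e-05, 0.3173, 0.1336),
    cis = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

test_that("sparse adjacency applies the strict Y < tau rule with |z| weights", {
  res <- fake_results(tiny_entries())
  y <- fake_measures(c(0.049, 0.3, 0.5, 0.05, 0.8, 0.9))
  adj <- build_sparse_adjacency(res, y, tau = 0.05, weighted = TRUE)
  expect_identical(nrow(adj$edges), 1L)        # Y = 0.05 is excluded (strict)
  expect_equal(adj$edges$weight, 3.2)          # |z| of the surviving edge
  expect_identical(adj$edges$snp_id, "s1")

  unw <- build_sparse_adjacency(res, y, tau = 0.06, weighted = FALSE)
  expect_true(all(unw$edges$weight == 1))
  expect_identical(nrow(unw$edges), 2L)        # Y = 0.05 now included

  expect_error(build_sparse_adjacency(res, y, tau = 0), "tau")
  expect_error(build_sparse_adjacency(res, fake_measures(c(0.1, 0.2)), 0.05),
               "aligned")
})

test_that("relaxing tau can only add edges", {
  sim <- make_sim(n_samples = 150, n_snps = 50, n_genes = 40, seed = 101)
  res <- map_eqtls(sim$geno, sim$expr, sim$X)
  y <- edge_measures(res, kind = "QV")
  key <- function(adj) paste(adj$edges$snp_id, adj$edges$gene_id)
  prev <- character(0)
  for (tau in c(0.05, 0.1, 0.15, 0.2)) {
    cur <- key(build_sparse_adjacency(res, y, tau = tau))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("dense adjacency carries every tested pair's p-value bit-exactly", {
  res <- fake_results(tiny_entries())
  adj <- build_dense_adjacency(res)
  expect_identical(nrow(adj$edges), 6L)
  expect_identical(adj$edges$weight, tiny_entries()$p)
  streamed <- fake_results(tiny_entries(), store = "streamed")
  expect_error(build_dense_adjacency(streamed), "incomplete|streamed")
})

test_that("sparse degree sums incident weights with cis/trans decomposition", {
  edges <- data.frame(snp_id = c("s1", "s1", "s2"),
                      gene_id = c("g1", "g2", "g1"),
                      weight = c(2.5, 3.5, 1.0),
                      cis = c(TRUE, FALSE, TRUE), stringsAsFactors = FALSE)
  adj <- structure(list(edges = edges, representation = "sparse-weighted",
                        tau = 0.05, weighted = TRUE, scope = "location-specific",
                        measure_kind = "BH",
                        snp_ids = c("s1", "s2", "s3"), gene_ids = c("g1", "g2")),
                   class = "adjacency_view")
  d <- degree_sparse(adj, "SNP")
  expect_equal(d$table$total, c(6.0, 1.0, 0))   # absent node s3 gets 0
  expect_equal(d$table$cis_part, c(2.5, 1.0, 0))
  expect_equal(d$table$trans_part, c(3.5, 0, 0))
  expect_equal(d$table$total, d$table$cis_part + d$table$trans_part)
  g <- degree_sparse(adj, "gene")
  expect_equal(g$table$total, c(3.5, 3.5))
})

test_that("sparse degree equals the dense-matrix row/column sums", {
  set.seed(5)
  n <- 150; m <- 180
  snps <- sprintf("s%03d", 1:n); genes <- sprintf("g%03d", 1:m)
  full <- matrix(0, n, m, dimnames = list(snps, genes))
  k <- 800
  idx <- cbind(sample(n, k, TRUE), sample(m, k, TRUE))
  idx <- idx[!duplicated(idx), , drop = FALSE]
  full[idx] <- abs(rnorm(nrow(idx))) + 0.1
  edges <- data.frame(snp_id = snps[idx[, 1]], gene_id = genes[idx[, 2]],
                      weight = full[idx], cis = rep(TRUE, nrow(idx)),
                      stringsAsFactors = FALSE)
  adj <- structure(list(edges = edges, representation = "sparse-weighted",
                        tau = 0.05, weighted = TRUE, scope = "location-specific",
                        measure_kind = "BH", snp_ids = snps, gene_ids = genes),
                   class = "adjacency_view")
  expect_equal(degree_sparse(adj, "SNP")$table$total, unname(rowSums(full)),
               tolerance = 1e-12)
  expect_equal(degree_sparse(adj, "gene")$table$total, unname(colSums(full)),
               tolerance = 1e-12)
})

test_that("NP degree is the per-node non-null proportion with a test floor", {
  set.seed(6)
  m <- 3000
  entries <- data.frame(
    snp_id = rep(c("null_snp", "hot_snp"), each = m),
    gene_id = rep(sprintf("g%04d", 1:m), 2),
    beta = 0, z = 0,
    p = c(runif(m), rep(1e-9, m)),
    cis = FALSE, stringsAsFactors = FALSE)
  adj <- build_dense_adjacency(fake_results(entries))
  d <- degree_np(adj, "SNP")
  expect_lte(d$table$total[d$table$node_id == "null_snp"], 0.1)
  expect_gte(d$table$total[d$table$node_id == "hot_snp"], 0.95)
  expect_true(all(d$table$total >= 0 & d$table$total <= 1))
  small <- build_dense_adjacency(fake_results(tiny_entries()))
  expect_error(degree_np(small, "SNP"), "fewer than")
})

test_that("top-quartile annotation uses the interpolated 75th percentile", {
  deg <- structure(list(table = data.frame(node_id = letters[1:8], total = 1:8,
                                           cis_part = 0, trans_part = 0),
                        axis = "SNP", weighted = TRUE, definition = "BH"),
                   class = "degree_vector")
  ann <- top_quartile_annotation(deg)
  expect_equal(ann$value, as.numeric(1:8 >= 6.25))
  expect_equal(sum(ann$value), 2)

  flat <- deg; flat$table$total <- rep(3, 8)
  expect_warning(ann2 <- top_quartile_annotation(flat), "degenerate")
  expect_true(all(ann2$value == 1))

  set.seed(9)
  cont <- deg; cont$table <- data.frame(node_id = sprintf("n%03d", 1:400),
                                        total = rnorm(400), cis_part = 0, trans_part = 0)
  a3 <- top_quartile_annotation(cont)
  expect_true(abs(mean(a3$value) - 0.25) <= 2 / 400)
})

test_that("gene-window annotation assigns the maximum overlapping gene degree", {
  geno <- genotype_matrix(
    matrix(rep(0:1, 4), nrow = 2,
           dimnames = list(NULL, c("sA", "sB", "sC", "sD"))),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    pos = c(90000L, 150000L, 260000L, 100000L))
  genes <- data.frame(gene_id = c("gLow", "gHigh"),
                      chrom = c("chr1", "chr1"),
                      tss = c(100000L, 140000L))
  deg <- structure(list(table = data.frame(node_id = c("gLow", "gHigh"),
                                           total = c(3, 5), cis_part = 0, trans_part = 0),
                        axis = "gene", weighted = TRUE, definition = "BH"),
                   class = "degree_vector")
  ann <- gene_window_annotation(deg, genes, geno, flank = 5e4)
  expect_equal(ann$value, c(5, 5, 0, 0))
  # sA: 10 kb upstream of gLow but also within 50 kb of gHigh -> max = 5
  # sC: 60 kb past every window -> 0; sD: other chromosome -> 0
  ann2 <- gene_window_annotation(deg, genes[1, , drop = FALSE], geno, flank = 5e4)
  expect_equal(ann2$value, c(3, 3, 0, 0))
})

test_that("the signed-weight transform is positive, increasing, and overflow-safe", {
  expect_equal(transform_regulatory_weights(0), log(2), tolerance = 1e-12)
  expect_equal(transform_regulatory_weights(10), 10.0000453988992, tolerance = 1e-10)
  expect_equal(transform_regulatory_weights(-10), 4.53988992168646e-05, tolerance = 1e-10)
  w <- seq(-30, 30, length.out = 241)
  out <- transform_regulatory_weights(w)
  expect_true(all(is.finite(out)) && all(out > 0))
  expect_true(all(diff(out) > 0))
  # extreme weights stay finite (log-sum-exp form; ln(e^w+1) would overflow)
  ext <- transform_regulatory_weights(c(-800, 800))
  expect_true(all(is.finite(ext)))
  expect_equal(ext[2], 800)
})

test_that("simulated degree distributions are right-skewed and weighting preserves ranks", {
  sim <- make_sim(n_samples = 250, n_snps = 120, n_genes = 60,
                  n_cis = 25, n_trans = 10, seed = 111)
  res <- map_eqtls(sim$geno, sim$expr, sim$X)
  y <- edge_measures(res, kind = "BH")
  adj_w <- build_sparse_adjacency(res, y, tau = 0.2, weighted = TRUE)
  adj_u <- build_sparse_adjacency(res, y, tau = 0.2, weighted = FALSE)
  dw <- degree_sparse(adj_w, "SNP")$table$total
  du <- degree_sparse(adj_u, "SNP")$table$total
  skew <- mean((dw - mean(dw))^3) / stats::sd(dw)^3
  expect_gt(skew, 0)
  expect_gt(stats::cor(dw, du, method = "spearman"), 0.8)
  # BH edges form a subset of QV edges when pi0-hat < 1 (QV q-values are
  # smaller); compared at matching global scope
  qv <- edge_measures(res, kind = "QV", scope = "global")
  bh_set <- paste(adj_w$edges$snp_id, adj_w$edges$gene_id)
  qv_set <- with(build_sparse_adjacency(res, qv, tau = 0.2)$edges,
                 paste(snp_id, gene_id))
  expect_true(all(bh_set %in% qv_set))
})
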