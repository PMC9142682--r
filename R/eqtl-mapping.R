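#' Classify SNP-gene pairs as cis or trans
#'
#' A pair is cis when SNP and gene TSS share a chromosome and the distance is
#' at most `window` (inclusive boundary); anything else, including any
#' cross-chromosome pair, is trans.
#'
#' @param snp_chrom,snp_pos SNP chromosome and 1-based position (bp).
#' @param gene_chrom,gene_pos Gene TSS chromosome and 1-based position (bp).
#' @param window Cis window in bp (default 1 Mb).
#' @return Logical vector, `TRUE` for cis.
#' @export
classify_cis_trans <- function(snp_chrom, snp_pos, gene_chrom, gene_pos,
                               window = 1e6) {
  snp_chrom == gene_chrom & abs(snp_pos - gene_pos) <= window
}

#' Exhaustive covariate-adjusted eQTL mapping
#'
#' Fits, for every SNP-gene pair, the linear model
#' `g_j = alpha_0 + X alpha + beta_ij s_i + e` by ordinary least squares and
#' reports the slope, its Wald statistic `z = beta / SE(beta)`, and a
#' two-sided p-value. Computation residualizes both dosages and expression on
#' the covariates (with intercept) first; by Frisch-Waugh this reproduces the
#' joint fit's slope and standard error. The Wald p-value uses the normal
#' reference by default to match the z-statistic edge weights used in network
#' construction; `df_method = "t"` uses the exact t reference instead.
#'
#' SNPs whose dosage is constant after covariate projection are untestable:
#' they are dropped from the result and from the test counts, and listed in
#' the `untestable` element.
#'
#' @param geno A [genotype_matrix()].
#' @param expr An [expression_matrix()] with identical sample ordering.
#' @param covariates Optional samples x c numeric covariate matrix (no
#'   intercept column; one is added). Must be full rank with the intercept.
#' @param cis_window Cis window in bp passed to [classify_cis_trans()].
#' @param store `"dense"` keeps every tested pair; `"streamed"` keeps all cis
#'   pairs plus trans pairs with `p <= p_keep`, while still recording the
#'   exact number of tests performed per stratum.
#' @param p_keep Trans p-value ceiling for streamed storage (default 1e-3).
#' @param df_method `"normal"` (default) or `"t"` for the Wald p-value.
#' @return An object of class `eqtl_result_set`: `entries` (data frame
#'   `snp_id`, `gene_id`, `beta`, `z`, `p`, `cis`), `n_tests_cis`,
#'   `n_tests_trans`, `store`, `snp_ids`, `gene_ids`, `untestable`, plus the
#'   coordinate vectors needed downstream.
#' @export
map_eqtls <- function(geno, expr, covariates = NULL,
                      cis_window = 1e6,
                      store = c("dense", "streamed"),
                      p_keep = 1e-3,
                      df_method = c("normal", "t")) {
  store <- match.arg(store)
  df_method <- match.arg(df_method)
  S <- geno$dosages
  G <- expr$values
  r <- nrow(S)
  if (nrow(G) != r) stop("genotype and expression sample counts differ")
  X <- cbind(`(Intercept)` = rep(1, r), covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("covariate matrix is rank deficient (with intercept)")
  c_fit <- ncol(X)
  if (r < c_fit + 2L) stop("need at least covariates + 3 samples")
  df <- r - c_fit - 1L

  S_res <- S - X %*% qr.coef(qx, S)
  G_res <- G - X %*% qr.coef(qx, G)
  ss_s <- colSums(S_res^2)
  ss_g <- colSums(G_res^2)

  testable <- ss_s > 1e-10 * r
  untestable <- geno$snp_ids[!testable]
  S_res <- S_res[, testable, drop = FALSE]
  ss_s <- ss_s[testable]
  snp_ids <- geno$snp_ids[testable]
  snp_chrom <- geno$chrom[testable]
  snp_pos <- geno$pos[testable]
  n <- length(snp_ids)
  m <- ncol(G)

  cp <- crossprod(S_res, G_res)               # n x m
  beta <- cp / ss_s
  rss <- outer(rep(1, n), ss_g) - beta * cp    # residual SS of the pair fit
  rss[rss < 0] <- 0
  se <- sqrt(rss / df / ss_s)
  z <- beta / se
  z[se == 0] <- sign(beta[se == 0]) * Inf
  p <- if (df_method == "normal") 2 * stats::pnorm(-abs(z)) else 2 * stats::pt(-abs(z), df = df)

  cis <- outer(snp_chrom, expr$tss_chrom, "==") &
    abs(outer(snp_pos, expr$tss_pos, "-")) <= cis_window

  n_tests_cis <- sum(cis)
  n_tests_trans <- n * m - n_tests_cis

  entries <- data.frame(
    snp_id = rep(snp_ids, times = m),
    gene_id = rep(expr$gene_ids, each = n),
    beta = as.numeric(beta),
    z = as.numeric(z),
    p = as.numeric(p),
    cis = as.logical(cis),
    stringsAsFactors = FALSE
  )
  if (store == "streamed") {
    entries <- entries[entries$cis | entries$p <= p_keep, , drop = FALSE]
    rownames(entries) <- NULL
  }
  structure(
    list(entries = entries,
         n_tests_cis = n_tests_cis, n_tests_trans = n_tests_trans,
         store = store, p_keep = if (store == "streamed") p_keep else NA_real_,
         df = df, df_method = df_method,
         snp_ids = snp_ids, gene_ids = expr$gene_ids,
         snp_chrom = snp_chrom, snp_pos = snp_pos,
         gene_chrom = expr$tss_chrom, gene_pos = expr$tss_pos,
         untestable = untestable),
    class = "eqtl_result_set"
  )
}

#' @export
print.eqtl_result_set <- function(x, ...) {
  cat(sprintf("eqtl_result_set (%s storage): %d entries; %d cis + %d trans tests over %d SNPs x %d genes\n",
              x$store, nrow(x$entries), x$n_tests_cis, x$n_tests_trans,
              length(x$snp_ids), length(x$gene_ids)))
  if (length(x$untestable)) {
    cat(sprintf("  %d SNP(s) untestable (zero variance after covariate projection)\n",
                length(x$untestable)))
  }
  invisible(x)
}

#' Write an eQTL result table to TSV
#'
#' Columns `snp_id, gene_id, beta, z, p, cis`, sorted by p within stratum.
#'
#' @param results An [map_eqtls()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_eqtl_tsv <- function(results, path) {
  e <- results$entries
  e <- e[order(!e$cis, e$p), , drop = FALSE]
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
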