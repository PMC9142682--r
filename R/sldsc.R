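#' LD scores from genotypes or an r-squared structure
#'
#' `l(j,c) = sum_k a_ck r^2_jk`, summing each annotation against the squared
#' Pearson correlation between SNP dosage vectors within a window of SNP `j`
#' (unadjusted r^2; the self term `r^2_jj = 1` is always included). With no
#' LD (`r2 = identity`) and a binary annotation, `l(j,c) = a_cj`.
#'
#' @param annotations SNP x annotation numeric matrix.
#' @param geno Optional [genotype_matrix()]; r^2 is computed between dosage
#'   columns within `window` bp on the same chromosome.
#' @param r2 Optional precomputed SNP x SNP squared-correlation matrix
#'   (overrides `geno`); `NULL` with `geno = NULL` means identity LD.
#' @param window LD window in bp (default 1 Mb).
#' @return Matrix of LD scores, SNPs x annotations.
#' @export
compute_ld_scores <- function(annotations, geno = NULL, r2 = NULL, window = 1e6) {
  a <- as.matrix(annotations)
  if (!is.null(r2)) {
    return(as.matrix(r2) %*% a)
  }
  if (is.null(geno)) {
    return(a)  # identity LD: self term only
  }
  dos <- geno$dosages
  sds <- apply(dos, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("%d zero-variance SNP(s) excluded from LD computation", sum(sds == 0)))
  }
  n_snp <- ncol(dos)
  if (nrow(a) != n_snp) stop("annotations must have one row per SNP")
  l <- a  # start from the self term
  for (ch in unique(geno$chrom)) {
    idx <- which(geno$chrom == ch)
    pos <- geno$pos[idx]
    for (ii in seq_along(idx)) {
      j <- idx[ii]
      if (sds[j] == 0) { l[j, ] <- 0; next }
      near <- idx[abs(pos - pos[ii]) <= window & idx != j & sds[idx] > 0]
      if (length(near) == 0L) next
      r <- suppressWarnings(stats::cor(dos[, j], dos[, near, drop = FALSE]))
      l[j, ] <- l[j, ] + as.numeric(r^2 %*% a[near, , drop = FALSE])
    }
  }
  l
}

# Delete-one-block jackknife over contiguous SNP blocks; est_fun(keep_idx)
# returns the statistic vector. Returns list(se, estimates).
block_jackknife <- function(n, n_blocks, est_fun) {
  blocks <- split(seq_len(n), cut(seq_len(n), breaks = n_blocks, labels = FALSE))
  full <- est_fun(seq_len(n))
  vals <- vapply(blocks, function(b) est_fun(setdiff(seq_len(n), b)),
                 numeric(length(full)))
  ests <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = 1L)
  b <- length(blocks)
  center <- colMeans(ests)
  se <- sqrt((b - 1) / b * colSums(sweep(ests, 2, center)^2))
  list(se = se, estimates = ests)
}

#' Stratified LD-score regression
#'
#' Fits the linear model `E[chi^2_j] = N sum_c l(j,c) tau_c + 1` by least
#' squares: with the intercept fixed at 1 (default), `chi^2 - 1` is
#' regressed through the origin on `N * l`; `intercept = "free"` estimates
#' the intercept too. Standard errors and p-values come from a
#' leave-one-block-out jackknife over contiguous SNP blocks.
#'
#' @param chisq Per-SNP chi-square statistics.
#' @param N_gwas GWAS sample size.
#' @param ldscores SNP x annotation LD-score matrix from
#'   [compute_ld_scores()].
#' @param intercept `"fixed-1"` (default) or `"free"`.
#' @param n_blocks Jackknife blocks (default 20).
#' @return Object of class `sldsc_fit`: `tau` (per-annotation estimates),
#'   `se`, `p` (normal approximation), `intercept_value`, `jackknife`
#'   (per-block estimates), `N`, `M` (SNP count), `ldscores`, `chisq`.
#' @export
sldsc_regress <- function(chisq, N_gwas, ldscores,
                          intercept = c("fixed-1", "free"),
                          n_blocks = 20L) {
  intercept <- match.arg(intercept)
  l <- as.matrix(ldscores)
  m <- length(chisq)
  if (nrow(l) != m) stop("chisq and ldscores must have one row per SNP")
  if (m < 2L * n_blocks) stop("need at least 2 SNPs per jackknife block")
  x <- N_gwas * l
  if (intercept == "free") x <- cbind(`(intercept)` = 1, x)
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    bad <- colnames(x)[qrx$pivot[seq(qrx$rank + 1L, ncol(x))]]
    stop(sprintf("collinear LD-score columns: %s", paste(bad, collapse = ", ")))
  }
  y <- chisq - 1
  est_fun <- function(keep) {
    as.numeric(qr.coef(qr(x[keep, , drop = FALSE]), y[keep]))
  }
  full <- est_fun(seq_len(m))
  jk <- block_jackknife(m, n_blocks, est_fun)
  names(full) <- colnames(x)
  se <- jk$se
  p <- 2 * stats::pnorm(-abs(full / se))
  if (intercept == "free") {
    icpt <- 1 + full[1]
    tau <- full[-1]; tau_se <- se[-1]; tau_p <- p[-1]
    jk_tau <- jk$estimates[, -1, drop = FALSE]
  } else {
    icpt <- 1
    tau <- full; tau_se <- se; tau_p <- p
    jk_tau <- jk$estimates
  }
  structure(
    list(tau = tau, se = tau_se, p = tau_p, intercept_value = icpt,
         jackknife = jk_tau, N = N_gwas, M = m, ldscores = l, chisq = chisq),
    class = "sldsc_fit"
  )
}

#' @export
print.sldsc_fit <- function(x, ...) {
  cat(sprintf("S-LDSC fit: %d SNPs, N = %g, intercept = %g\n", x$M, x$N, x$intercept_value))
  print(data.frame(tau = x$tau, se = x$se, p = x$p))
  invisible(x)
}

#' Standardized per-SD effect size tau*
#'
#' `tau* = tau_c sd(c) / (h2_g / M)`: the proportionate change in per-SNP
#' heritability per standard deviation of the annotation, comparable across
#' annotations and traits.
#'
#' @param tau_c Annotation coefficient (per-SNP heritability units).
#' @param annotation Annotation values over the M SNPs.
#' @param h2 Total SNP heritability (> 0).
#' @param M SNP count (> 0).
#' @return Unitless tau*.
#' @export
tau_star <- function(tau_c, annotation, h2, M) {
  if (h2 <= 0 || M <= 0) stop("h2 and M must be positive")
  s <- stats::sd(annotation)
  if (s == 0) {
    warning("constant annotation: sd = 0, tau* set to 0")
    return(0)
  }
  tau_c * s / (h2 / M)
}

#' Heritability enrichment of an annotation
#'
#' Enrichment is the proportion of SNP heritability captured by the
#' annotation divided by the proportion of (annotation mass over) SNPs:
#' `[h2(C)/h2_g] / [sum_j a_jc / M]`, with per-SNP variance decomposed as
#' `Var(beta_j) = sum_c a_cj tau_c`. The all-ones annotation has enrichment
#' exactly 1. Standard errors and p-values (for enrichment != 1) use the
#' fit's leave-one-block-out jackknife tau estimates.
#'
#' @param fit An [sldsc_regress()] result.
#' @param annotations The SNP x annotation matrix the LD scores were built
#'   from (per-SNP variance uses annotation values, not LD scores).
#' @param which_c Annotation to evaluate (column index or name).
#' @return List: `enrichment`, `se`, `p`, `h2_total`, `h2_annot`,
#'   `prop_snps`, `tau_star` (with jackknife `tau_star_se`).
#' @export
enrichment <- function(fit, annotations, which_c = 1L) {
  a <- as.matrix(annotations)
  if (nrow(a) != fit$M) stop("annotations must have one row per SNP")
  ac <- a[, which_c]
  if (sum(ac) <= 0) stop("annotation has no mass")
  enr_of <- function(tau) {
    var_beta <- as.numeric(a %*% tau)
    h2g <- sum(var_beta)
    if (h2g <= 0) return(c(NaN, NaN, h2g))
    h2c <- sum(ac * var_beta)
    unname(c((h2c / h2g) / (sum(ac) / fit$M),
             tau[which_c] * stats::sd(ac) / (h2g / fit$M), h2g))
  }
  full <- enr_of(fit$tau)
  if (!is.finite(full[1])) stop("total heritability is not positive")
  jk <- t(apply(fit$jackknife, 1, enr_of))
  b <- nrow(jk)
  se2 <- (b - 1) / b * colSums(sweep(jk, 2, colMeans(jk))^2)
  se <- sqrt(se2)
  p <- if (se[1] == 0) {
    if (full[1] == 1) 1 else 0  # degenerate jackknife (e.g. all-ones annotation)
  } else {
    2 * stats::pnorm(-abs((full[1] - 1) / se[1]))
  }
  list(enrichment = full[1], se = se[1], p = p,
       h2_total = full[3],
       h2_annot = full[1] * full[3] * sum(ac) / fit$M,
       prop_snps = sum(ac) / fit$M,
       tau_star = full[2], tau_star_se = se[2])
}
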