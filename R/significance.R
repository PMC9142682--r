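#' Estimate the null proportion pi0 from p-values
#'
#' Computes `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))` over a lambda
#' grid and, with `method = "smoother"`, extrapolates a cubic smoothing
#' spline to `lambda = 1`. When the smoother misbehaves (non-finite or
#' non-positive prediction) the estimate at the largest grid lambda is used.
#' The estimate is floored at `1/m` and capped at 1.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @param lambda_grid Grid in `[0, 1)`; default `seq(0.05, 0.95, by = 0.05)`.
#' @param method `"smoother"` (default) or `"fixed"` (use the single largest
#'   grid value only).
#' @return A single estimate in `(0, 1]`.
#' @export
estimate_pi0 <- function(p, lambda_grid = seq(0.05, 0.95, by = 0.05),
                         method = c("smoother", "fixed")) {
  method <- match.arg(method)
  if (length(p) == 0L) stop("empty p-value vector")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  lambda_grid <- sort(lambda_grid)
  pi0_lambda <- vapply(lambda_grid, function(l) mean(p > l) / (1 - l), numeric(1))
  pi0 <- if (method == "fixed" || length(lambda_grid) < 4L) {
    pi0_lambda[length(pi0_lambda)]
  } else {
    fit <- try(stats::smooth.spline(lambda_grid, pi0_lambda, df = 3), silent = TRUE)
    est <- if (inherits(fit, "try-error")) NA_real_ else stats::predict(fit, x = 1)$y
    if (!is.finite(est) || est <= 0) pi0_lambda[length(pi0_lambda)] else est
  }
  min(max(pi0, 1 / m), 1)
}

#' Storey q-values
#'
#' `q(p_i) = min_{t >= p_i} pi0 * m * t / #\{p <= t\}`, computed as the
#' running minimum from the largest p-value downward. With `pi0 = 1` this is
#' exactly the Benjamini-Hochberg step-up adjustment.
#'
#' @param p Numeric p-values.
#' @param lambda_grid,pi0_method Passed to [estimate_pi0()].
#' @param pi0 Optional fixed override for the null proportion.
#' @return List with `qvalues` (same order as `p`) and `pi0`.
#' @export
storey_qvalue <- function(p, lambda_grid = seq(0.05, 0.95, by = 0.05),
                          pi0_method = c("smoother", "fixed"), pi0 = NULL) {
  if (length(p) == 0L) stop("empty p-value vector")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  pi0_method <- match.arg(pi0_method)
  m <- length(p)
  if (is.null(pi0)) pi0 <- estimate_pi0(p, lambda_grid, pi0_method)
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(pi0 * m * p[o] / seq(m, 1)))
  out <- numeric(m)
  out[o] <- q
  list(qvalues = out, pi0 = pi0)
}

#' Streamed top-K adaptation of Benjamini-Hochberg
#'
#' Computes FDR q-values from only the `K` smallest p-values of `N` total
#' tests via the recursion `q_K = (N/K) p_K`,
#' `q_i = min((N/i) p_i, q_{i+1})`, so exhaustive result sets need not be
#' stored. With `K = N` this equals the classical BH step-up adjustment.
#' Outputs are clamped to 1 (the raw recursion can exceed it).
#'
#' @param p_sorted Ascending p-values `p_1 <= ... <= p_K`.
#' @param N_total Total number of tests performed (`K <= N_total`).
#' @return Nondecreasing q-values of length `K`, in `[0, 1]`.
#' @export
bh_adapted <- function(p_sorted, N_total) {
  K <- length(p_sorted)
  if (K == 0L) stop("empty p-value vector")
  if (is.unsorted(p_sorted)) stop("p-values must be in ascending order")
  if (K > N_total) stop("K must not exceed N_total")
  pmin(1, rev(cummin(rev(N_total / seq_len(K) * p_sorted))))
}

#' Local false discovery rate by Lindsey's method
#'
#' Estimates `lfdr(z) = pi0 f0(z) / f(z)`, the posterior probability that a
#' test with statistic `z` is null. The marginal density `f` is estimated by
#' Lindsey's method: histogram counts are fit by a Poisson log-linear model
#' in a natural-spline basis of the bin midpoints. The null `f0` is standard
#' normal by default; `null = "empirical"` recenters/rescales it by the
#' median and the interquartile range of `z` (central matching). `pi0` is
#' estimated from the two-sided normal p-values unless overridden. Results
#' are clamped to `[0, 1]`; `monotone = TRUE` additionally enforces
#' nonincreasing lfdr in `|z|` by isotonic regression.
#'
#' @param z Numeric z-statistics; at least `min_n` values.
#' @param null `"theoretical"` (standard normal) or `"empirical"`.
#' @param pi0 Optional fixed null proportion.
#' @param n_bins Histogram bins (default 120).
#' @param df Spline degrees of freedom (default 7).
#' @param monotone Enforce nonincreasing lfdr in `|z|` (default `FALSE`).
#' @param min_n Minimum number of statistics required (default 200).
#' @return List with `lfdr` (aligned to `z`), `pi0`, `null`.
#' @export
local_fdr <- function(z, null = c("theoretical", "empirical"), pi0 = NULL,
                      n_bins = 120L, df = 7L, monotone = FALSE, min_n = 200L) {
  null <- match.arg(null)
  z <- as.numeric(z)
  if (length(z) < min_n) {
    stop(sprintf("need at least %d statistics for density estimation", min_n))
  }
  if (stats::sd(z) == 0) stop("degenerate (constant) z-statistics")
  breaks <- seq(min(z) - 1e-8, max(z) + 1e-8, length.out = n_bins + 1L)
  h <- hist(z, breaks = breaks, plot = FALSE)
  mids <- h$mids
  width <- diff(breaks)[1]
  basis <- splines::ns(mids, df = df)
  # sparse tail bins routinely trip glm convergence warnings; the fitted
  # density is still usable (and clamped downstream)
  fit <- suppressWarnings(stats::glm(h$counts ~ basis, family = stats::poisson()))
  zb <- stats::predict(basis, z)
  eta <- cbind(1, zb) %*% stats::coef(fit)
  f_hat <- exp(as.numeric(eta)) / (length(z) * width)
  if (null == "theoretical") {
    mu0 <- 0; sd0 <- 1
  } else {
    mu0 <- stats::median(z)
    sd0 <- stats::IQR(z) / (2 * stats::qnorm(0.75))
  }
  if (is.null(pi0)) {
    p <- 2 * stats::pnorm(-abs((z - mu0) / sd0))
    pi0 <- estimate_pi0(p)
  }
  lfdr <- pmin(1, pmax(0, pi0 * stats::dnorm(z, mu0, sd0) / f_hat))
  if (monotone) {
    a <- abs(z - mu0)
    ord <- order(a)
    iso <- stats::isoreg(a[ord], -lfdr[ord])
    lfdr[ord] <- pmin(1, pmax(0, -iso$yf))
  }
  list(lfdr = lfdr, pi0 = pi0, null = null)
}

#' Non-null proportion of a p-value set
#'
#' `1 - pi0` with the same pi0 estimator as [storey_qvalue()], clamped to
#' `[0, 1]`. Used as the dense-network degree: a node's degree is the
#' estimated proportion of its association tests that are non-null.
#'
#' @param p Numeric p-values.
#' @param ... Passed to [estimate_pi0()].
#' @return Value in `[0, 1]`.
#' @export
nonnull_proportion <- function(p, ...) {
  min(max(1 - estimate_pi0(p, ...), 0), 1)
}

#' Attach an edge-significance measure to eQTL results
#'
#' Computes the measure `Y` used for sparse-network thresholding, honoring
#' the scoping conventions of the analysis: Storey q-values (`"QV"`) and
#' local FDR (`"LFDR"`) are computed per SNP across that SNP's genes by
#' default, while the streamed Benjamini-Hochberg adaptation (`"BH"`) is
#' computed globally per stratum with the exact test counts as `N`. In
#' location-specific mode the cis and trans test sets are treated separately;
#' genome-wide mode pools them.
#'
#' @param results An [map_eqtls()] result. QV and LFDR require dense storage
#'   (their per-node p-vectors must be complete); BH accepts streamed
#'   storage and uses the recorded stratum test counts.
#' @param kind `"BH"`, `"QV"`, or `"LFDR"`.
#' @param scope `"default"` (per-SNP for QV/LFDR, global for BH),
#'   `"per-snp"`, `"per-gene"`, or `"global"`.
#' @param strata `"location-specific"` (separate cis/trans, default) or
#'   `"genome-wide"` (pooled).
#' @return Object of class `significance_table`: `measure` (numeric Y
#'   aligned to `results$entries`), `kind`, `scope`, `strata`, `pi0` (named
#'   estimates where applicable).
#' @export
edge_measures <- function(results,
                          kind = c("BH", "QV", "LFDR"),
                          scope = c("default", "per-snp", "per-gene", "global"),
                          strata = c("location-specific", "genome-wide")) {
  kind <- match.arg(kind)
  scope <- match.arg(scope)
  strata <- match.arg(strata)
  if (scope == "default") scope <- if (kind == "BH") "global" else "per-snp"
  e <- results$entries
  if (kind %in% c("QV", "LFDR") && results$store != "dense") {
    stop(sprintf("%s requires dense storage: per-node statistic vectors must be complete", kind))
  }
  y <- rep(NA_real_, nrow(e))
  pi0 <- c()

  groups <- if (strata == "location-specific") {
    split(seq_len(nrow(e)), e$cis)
  } else {
    list(all = seq_len(nrow(e)))
  }
  stratum_total <- function(is_cis_group) {
    if (strata == "genome-wide") results$n_tests_cis + results$n_tests_trans
    else if (is_cis_group) results$n_tests_cis else results$n_tests_trans
  }

  for (gname in names(groups)) {
    idx <- groups[[gname]]
    if (length(idx) == 0L) next
    is_cis_group <- strata == "location-specific" && gname == "TRUE"
    if (kind == "BH" && scope == "global") {
      N <- stratum_total(is_cis_group)
      o <- idx[order(e$p[idx])]
      y[o] <- bh_adapted(e$p[o], N_total = N)
    } else {
      key <- if (scope == "per-gene") e$gene_id[idx] else e$snp_id[idx]
      if (scope == "global") key <- rep("all", length(idx))
      for (sub in split(idx, key)) {
        if (kind == "LFDR") {
          fit <- local_fdr(e$z[sub], min_n = min(200L, length(sub)))
          y[sub] <- fit$lfdr
        } else if (kind == "QV") {
          fit <- storey_qvalue(e$p[sub])
          y[sub] <- fit$qvalues
        } else { # per-node BH variant
          o <- sub[order(e$p[sub])]
          y[o] <- bh_adapted(e$p[o], N_total = length(sub))
        }
      }
    }
  }
  structure(
    list(measure = y, kind = kind, scope = scope, strata = strata),
    class = "significance_table"
  )
}
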