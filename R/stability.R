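#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties averaged). A constant input
#' vector makes the correlation undefined; `NaN` is returned with a warning.
#'
#' @param x,y Paired numeric vectors, length at least 3.
#' @return Correlation in `[-1, 1]`, or `NaN` when undefined.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(NaN)
  }
  stats::cor(x, y, method = "spearman")
}

#' Median and interquartile range
#'
#' Summary convention for correlation collections: median and `Q3 - Q1` with
#' linear-interpolation quantiles.
#'
#' @param values Numeric vector, length at least 1.
#' @return Named numeric `c(median = ..., iqr = ...)`.
#' @export
summarize_median_iqr <- function(values) {
  if (length(values) == 0L) stop("empty value vector")
  q <- as.numeric(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, na.rm = TRUE))
  c(median = q[2], iqr = q[3] - q[1])
}

#' Correlation of degree between two networks
#'
#' Spearman correlation over the shared node set. The default inclusion rule
#' keeps every node present in both degree vectors, including zero-degree
#' nodes (ties are handled by average ranks); `"nonzero"` restricts to nodes
#' with nonzero degree in at least one network.
#'
#' @param deg_a,deg_b `degree_vector` objects (same axis).
#' @param inclusion `"shared"` (default) or `"nonzero"`.
#' @param component Degree column to correlate: `"total"`, `"cis_part"`, or
#'   `"trans_part"`.
#' @return List with `rho` and `n` (number of nodes used).
#' @export
cross_network_correlation <- function(deg_a, deg_b,
                                      inclusion = c("shared", "nonzero"),
                                      component = c("total", "cis_part", "trans_part")) {
  inclusion <- match.arg(inclusion)
  component <- match.arg(component)
  shared <- intersect(deg_a$table$node_id, deg_b$table$node_id)
  if (length(shared) == 0L) stop("no shared nodes between the two networks")
  a <- deg_a$table[match(shared, deg_a$table$node_id), component]
  b <- deg_b$table[match(shared, deg_b$table$node_id), component]
  if (inclusion == "nonzero") {
    keep <- a != 0 | b != 0
    a <- a[keep]; b <- b[keep]
  }
  if (length(a) < 3L) stop("fewer than 3 nodes after applying the inclusion rule")
  list(rho = spearman_rho(a, b), n = length(a))
}

#' Random-effects meta-analysis of correlations
#'
#' Fisher z-transforms each correlation (variance `1/(n-3)`), pools with a
#' DerSimonian-Laird random-effects model, and back-transforms the pooled
#' estimate and its 95% CI with `tanh`.
#'
#' @param rho Per-study correlations.
#' @param n Per-study sample sizes (each > 3).
#' @return Object of class `meta_analysis_result`: `pooled`, `ci_lower`,
#'   `ci_upper`, `tau2` (between-study variance on the z scale), and the
#'   per-study inputs.
#' @export
random_effects_meta <- function(rho, n) {
  if (length(rho) != length(n)) stop("rho and n must have equal length")
  if (length(rho) < 2L) stop("need at least 2 studies")
  if (any(n <= 3)) stop("every study needs n > 3 for the Fisher-z variance")
  # |rho| = 1 has infinite Fisher z; clamp just inside so pooling stays finite
  zi <- atanh(pmin(pmax(rho, -1 + 1e-10), 1 - 1e-10))
  vi <- 1 / (n - 3)
  fit <- metafor::rma(yi = zi, vi = vi, method = "DL", test = "z")
  structure(
    list(pooled = tanh(as.numeric(fit$beta)),
         ci_lower = tanh(fit$ci.lb), ci_upper = tanh(fit$ci.ub),
         tau2 = fit$tau2, rho = rho, n = n),
    class = "meta_analysis_result"
  )
}

#' @export
print.meta_analysis_result <- function(x, ...) {
  cat(sprintf("random-effects meta-analysis of %d correlations: pooled rho = %.3f (95%% CI %.3f, %.3f), tau2 = %.4g\n",
              length(x$rho), x$pooled, x$ci_lower, x$ci_upper, x$tau2))
  invisible(x)
}

# Run mapping -> measure -> adjacency -> degree on one sample subset.
# Returns degree_vector(s) for the requested axes.
half_pipeline <- function(geno, expr, covariates, idx, config) {
  g <- geno
  g$dosages <- g$dosages[idx, , drop = FALSE]
  g$maf <- pmin(colMeans(g$dosages) / 2, 1 - colMeans(g$dosages) / 2)
  e <- expr
  e$values <- e$values[idx, , drop = FALSE]
  x <- if (is.null(covariates)) NULL else covariates[idx, , drop = FALSE]
  res <- map_eqtls(g, e, x, cis_window = config$cis_window, store = "dense")
  if (config$definition == "NP") {
    adj <- build_dense_adjacency(res)
    lapply(stats::setNames(config$axes, config$axes),
           function(ax) degree_np(adj, axis = ax, min_tests = config$np_min_tests))
  } else {
    meas <- edge_measures(res, kind = config$definition, strata = config$strata)
    adj <- build_sparse_adjacency(res, meas, tau = config$tau,
                                  weighted = config$weighted)
    lapply(stats::setNames(config$axes, config$axes),
           function(ax) degree_sparse(adj, axis = ax))
  }
}

#' Split-sample degree reproducibility
#'
#' The within-dataset reproducibility protocol: the samples are randomly
#' split into two (near-)equal disjoint halves, the full pipeline (mapping,
#' significance measure, adjacency, degree) is run independently on each
#' half, and the Spearman correlation between the two halves' degree vectors
#' is recorded. Repeated `n_repeats` times with fresh splits.
#'
#' For sparse definitions the correlation is reported for the full degree
#' and its cis/trans components; the dense NP degree is genome-wide only.
#'
#' @param geno,expr,covariates Inputs as for [map_eqtls()].
#' @param definition `"BH"`, `"QV"`, `"LFDR"`, or `"NP"`.
#' @param tau Sparse threshold (ignored for NP).
#' @param weighted Use `|z|` weights (ignored for NP).
#' @param axes Degree axes to evaluate, subset of `c("SNP", "gene")`.
#' @param strata Measure stratification passed to [edge_measures()].
#' @param cis_window Cis window (bp).
#' @param n_repeats Number of random splits (default 5).
#' @param np_min_tests Floor for [degree_np()].
#' @param seed Integer seed; the whole report is deterministic given it.
#' @return Object of class `split_stability_report`: `detail` (data frame:
#'   `repeat_id`, `axis`, `stratum`, `rho`, `n_nodes`) and `summary` (mean
#'   rho per axis x stratum).
#' @export
split_sample_stability <- function(geno, expr, covariates = NULL,
                                   definition = "BH", tau = 0.05,
                                   weighted = TRUE,
                                   axes = c("SNP", "gene"),
                                   strata = "location-specific",
                                   cis_window = 1e6,
                                   n_repeats = 5L,
                                   np_min_tests = 10L,
                                   seed = 1L) {
  r <- nrow(geno$dosages)
  if (r < 6L) stop("need at least 6 samples to split")
  config <- list(definition = definition, tau = tau, weighted = weighted,
                 axes = axes, strata = strata, cis_window = cis_window,
                 np_min_tests = np_min_tests)
  strata_cols <- if (definition == "NP") "total" else c("total", "cis_part", "trans_part")
  stratum_name <- c(total = "full", cis_part = "cis", trans_part = "trans")

  splits <- with_seed(seed, {
    lapply(seq_len(n_repeats), function(k) sample.int(r, ceiling(r / 2)))
  })
  rows <- list()
  for (k in seq_len(n_repeats)) {
    half1 <- splits[[k]]
    half2 <- setdiff(seq_len(r), half1)
    d1 <- tryCatch(half_pipeline(geno, expr, covariates, half1, config),
                   error = function(e) stop(sprintf("repeat %d, half 1: %s", k, conditionMessage(e))))
    d2 <- tryCatch(half_pipeline(geno, expr, covariates, half2, config),
                   error = function(e) stop(sprintf("repeat %d, half 2: %s", k, conditionMessage(e))))
    for (ax in axes) {
      ta <- d1[[ax]]$table; tb <- d2[[ax]]$table
      # a half may drop SNPs that are untestable within it; use shared nodes
      shared <- intersect(ta$node_id, tb$node_id)
      ia <- match(shared, ta$node_id); ib <- match(shared, tb$node_id)
      for (col in strata_cols) {
        rho <- suppressWarnings(spearman_rho(ta[[col]][ia], tb[[col]][ib]))
        rows[[length(rows) + 1L]] <- data.frame(
          repeat_id = k, axis = ax, stratum = stratum_name[[col]],
          rho = rho, n_nodes = length(shared), stringsAsFactors = FALSE)
      }
    }
  }
  detail <- do.call(rbind, rows)
  summary <- stats::aggregate(rho ~ axis + stratum, data = detail,
                              FUN = function(v) mean(v, na.rm = TRUE),
                              na.action = stats::na.pass)
  structure(
    list(detail = detail, summary = summary,
         definition = definition, tau = tau, weighted = weighted,
         n_repeats = n_repeats, seed = seed),
    class = "split_stability_report"
  )
}

#' @export
print.split_stability_report <- function(x, ...) {
  cat(sprintf("split-sample stability (%s%s%s, %d repeats):\n",
              x$definition,
              if (x$definition != "NP") sprintf(", tau=%g", x$tau) else "",
              if (x$weighted && x$definition != "NP") ", weighted" else "",
              x$n_repeats))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
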