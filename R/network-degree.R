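#' Build a sparse bipartite adjacency from thresholded measures
#'
#' An edge joins SNP i and gene j iff its significance measure satisfies
#' `Y < tau` (strict inequality); the edge weight is `|z|` when `weighted`,
#' else 1.
#'
#' @param results An [map_eqtls()] result.
#' @param measures An [edge_measures()] result aligned to `results$entries`.
#' @param tau Threshold, conventionally one of 0.05, 0.1, 0.15, 0.2; any
#'   value in `(0, 1)` is accepted.
#' @param weighted Use `|z|` edge weights (default `TRUE`).
#' @param scope `"location-specific"` (cis/trans tracked per edge, default)
#'   or `"genome-wide"`.
#' @return Object of class `adjacency_view`: `edges` (data frame `snp_id`,
#'   `gene_id`, `weight`, `cis`), `representation`, `tau`, `weighted`,
#'   `scope`, `measure_kind`, `snp_ids`, `gene_ids` (the full node
#'   universes, so zero-degree nodes are representable).
#' @export
build_sparse_adjacency <- function(results, measures, tau = 0.05,
                                   weighted = TRUE,
                                   scope = c("location-specific", "genome-wide")) {
  scope <- match.arg(scope)
  if (tau <= 0 || tau >= 1) stop("tau must lie in (0, 1)")
  if (length(measures$measure) != nrow(results$entries)) {
    stop("measures are not aligned to the result entries")
  }
  keep <- which(measures$measure < tau)
  e <- results$entries[keep, c("snp_id", "gene_id", "z", "cis"), drop = FALSE]
  edges <- data.frame(
    snp_id = e$snp_id, gene_id = e$gene_id,
    weight = if (weighted) abs(e$z) else rep(1, nrow(e)),
    cis = e$cis, stringsAsFactors = FALSE
  )
  rownames(edges) <- NULL
  structure(
    list(edges = edges,
         representation = if (weighted) "sparse-weighted" else "sparse-unweighted",
         tau = tau, weighted = weighted, scope = scope,
         measure_kind = measures$kind,
         snp_ids = results$snp_ids, gene_ids = results$gene_ids),
    class = "adjacency_view"
  )
}

#' Build the dense p-value adjacency
#'
#' All tested pairs are retained with the nominal p-value as the entry;
#' streamed (incomplete) result sets are rejected because every node's
#' p-vector must be complete for the non-null-proportion degree.
#'
#' @param results A dense-stored [map_eqtls()] result.
#' @return Object of class `adjacency_view` with `representation = "dense-p"`
#'   and `edges` columns `snp_id`, `gene_id`, `weight` (= p), `cis`.
#' @export
build_dense_adjacency <- function(results) {
  if (results$store != "dense") {
    stop("dense adjacency requires dense-stored results (streamed storage is incomplete)")
  }
  e <- results$entries
  edges <- data.frame(snp_id = e$snp_id, gene_id = e$gene_id,
                      weight = e$p, cis = e$cis, stringsAsFactors = FALSE)
  structure(
    list(edges = edges, representation = "dense-p", tau = NA_real_,
         weighted = FALSE, scope = "genome-wide", measure_kind = "NP-input",
         snp_ids = results$snp_ids, gene_ids = results$gene_ids),
    class = "adjacency_view"
  )
}

#' @export
print.adjacency_view <- function(x, ...) {
  cat(sprintf("adjacency_view (%s%s): %d edges over %d SNPs x %d genes\n",
              x$representation,
              if (!is.na(x$tau)) sprintf(", tau=%g, %s", x$tau, x$measure_kind) else "",
              nrow(x$edges), length(x$snp_ids), length(x$gene_ids)))
  invisible(x)
}

#' Degree of each node in a sparse adjacency
#'
#' Per-node sum of incident edge weights (a plain edge count when
#' unweighted), with cis and trans components reported separately under
#' location-specific scope. Nodes with no edges get degree 0.
#'
#' @param adj A sparse [build_sparse_adjacency()] result.
#' @param axis `"SNP"` or `"gene"`.
#' @return Object of class `degree_vector`: data-frame `table` with columns
#'   `node_id`, `total`, `cis_part`, `trans_part`, plus `axis`, `weighted`,
#'   `definition`.
#' @export
degree_sparse <- function(adj, axis = c("SNP", "gene")) {
  axis <- match.arg(axis)
  if (!startsWith(adj$representation, "sparse")) {
    stop("degree_sparse requires a sparse adjacency")
  }
  ids <- if (axis == "SNP") adj$snp_ids else adj$gene_ids
  key <- if (axis == "SNP") adj$edges$snp_id else adj$edges$gene_id
  f <- factor(key, levels = ids)
  sum_by <- function(w, which) {
    v <- numeric(length(ids))
    if (any(which)) {
      s <- rowsum(w[which], f[which])
      v[match(rownames(s), ids)] <- s[, 1]
    }
    v
  }
  w <- adj$edges$weight
  cis_part <- sum_by(w, adj$edges$cis)
  trans_part <- sum_by(w, !adj$edges$cis)
  structure(
    list(table = data.frame(node_id = ids, total = cis_part + trans_part,
                            cis_part = cis_part, trans_part = trans_part,
                            stringsAsFactors = FALSE),
         axis = axis, weighted = adj$weighted, definition = adj$measure_kind),
    class = "degree_vector"
  )
}

#' Non-null-proportion degree from the dense adjacency
#'
#' Each node's degree is `1 - pi0` estimated from its complete incident
#' p-value vector, i.e. the estimated proportion of the node's association
#' tests that are non-null. Defined genome-wide only (no cis/trans split).
#'
#' @param adj A dense [build_dense_adjacency()] result.
#' @param axis `"SNP"` or `"gene"`.
#' @param min_tests Minimum incident tests per node (default 10).
#' @return A `degree_vector` with `total` in `[0, 1]` and zero cis/trans
#'   parts (the dense degree is not location-decomposable).
#' @export
degree_np <- function(adj, axis = c("SNP", "gene"), min_tests = 10L) {
  axis <- match.arg(axis)
  if (adj$representation != "dense-p") stop("degree_np requires the dense p-value adjacency")
  ids <- if (axis == "SNP") adj$snp_ids else adj$gene_ids
  key <- if (axis == "SNP") adj$edges$snp_id else adj$edges$gene_id
  groups <- split(adj$edges$weight, factor(key, levels = ids))
  sizes <- lengths(groups)
  if (any(sizes < min_tests)) {
    stop(sprintf("node with fewer than %d incident tests (smallest: %d)",
                 min_tests, min(sizes)))
  }
  total <- vapply(groups, nonnull_proportion, numeric(1))
  structure(
    list(table = data.frame(node_id = ids, total = as.numeric(total),
                            cis_part = 0, trans_part = 0,
                            stringsAsFactors = FALSE),
         axis = axis, weighted = FALSE, definition = "NP"),
    class = "degree_vector"
  )
}

#' @export
print.degree_vector <- function(x, ...) {
  cat(sprintf("degree_vector (%s, %s%s): %d nodes, degree range [%g, %g]\n",
              x$axis, x$definition, if (x$weighted) ", weighted" else "",
              nrow(x$table), min(x$table$total), max(x$table$total)))
  invisible(x)
}

#' Binary top-quartile annotation of a degree vector
#'
#' Value 1 iff the node's degree is at least the 75th percentile
#' (linear-interpolation quantile), else 0. Used as the SNP-level heritability
#' annotation; binary for stable enrichment estimates.
#'
#' @param deg A `degree_vector` (at least 4 nodes).
#' @return Object of class `annotation_vector`: data frame `snp_ids`/`value`
#'   wrapped with `kind = "snp-top-quartile"`.
#' @export
top_quartile_annotation <- function(deg) {
  d <- deg$table$total
  if (length(d) < 4L) stop("need at least 4 nodes")
  if (max(d) == min(d)) {
    warning("all degrees equal: degenerate annotation (all nodes annotated)")
    value <- rep(1, length(d))
  } else {
    q75 <- as.numeric(stats::quantile(d, 0.75, type = 7))
    value <- as.numeric(d >= q75)
  }
  structure(
    list(snp_ids = deg$table$node_id, value = value, kind = "snp-top-quartile"),
    class = "annotation_vector"
  )
}

#' Continuous gene-window annotation of SNPs
#'
#' Annotates every SNP lying within a gene span (or TSS point) plus/minus
#' `flank` bp with that gene's degree; SNPs covered by several windows take
#' the maximum degree, SNPs in none get 0.
#'
#' @param gene_deg A gene-axis `degree_vector`.
#' @param genes Data frame with `gene_id`, `chrom`, and either `start`/`end`
#'   (gene span, 1-based inclusive) or `tss` (point geometry).
#' @param geno A [genotype_matrix()] supplying SNP coordinates.
#' @param flank Window flank in bp (default 50 kb).
#' @return An `annotation_vector` with `kind = "gene-window"`.
#' @export
gene_window_annotation <- function(gene_deg, genes, geno, flank = 5e4) {
  deg <- gene_deg$table$total[match(genes$gene_id, gene_deg$table$node_id)]
  keep <- !is.na(deg)
  genes <- genes[keep, , drop = FALSE]
  deg <- deg[keep]
  if (all(c("start", "end") %in% names(genes))) {
    start <- genes$start; end <- genes$end
  } else {
    start <- genes$tss; end <- genes$tss
  }
  windows <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = pmax(1, start - flank), end = end + flank)
  )
  snps <- GenomicRanges::GRanges(
    seqnames = geno$chrom,
    ranges = IRanges::IRanges(start = geno$pos, width = 1)
  )
  hits <- GenomicRanges::findOverlaps(snps, windows)
  value <- numeric(length(geno$snp_ids))
  if (length(hits) > 0L) {
    mx <- tapply(deg[S4Vectors::subjectHits(hits)],
                 S4Vectors::queryHits(hits), max)
    value[as.integer(names(mx))] <- as.numeric(mx)
  }
  structure(
    list(snp_ids = geno$snp_ids, value = value, kind = "gene-window"),
    class = "annotation_vector"
  )
}

#' Positive transform for signed regulatory-network edge weights
#'
#' `W = ln(e^w + 1)`: strictly positive and strictly increasing, mapping
#' signed regulatory edge weights onto a positive scale before degree
#' summation. Evaluated in log-sum-exp form so large `|w|` does not overflow.
#'
#' @param w Numeric edge weights (any sign).
#' @return Transformed weights, same length.
#' @export
transform_regulatory_weights <- function(w) {
  # log(exp(w) + 1) = max(w, 0) + log1p(exp(-|w|))
  pmax(w, 0) + log1p(exp(-abs(w)))
}
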