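#' Per-site nucleotide diversity of a haplotype alignment
#'
#' `pi = [sum_s 2 j_s (h - j_s) / (h (h - 1))] / L` where `j_s` is the
#' derived-allele count at segregating site `s`, `h` the number of
#' haplotypes, and `L` the locus length in bp. Monomorphic positions
#' contribute 0 to the numerator but are included in `L`. The per-site folded
#' term `j(h-j)` makes the statistic invariant to ancestral/derived
#' relabeling, and it equals the mean pairwise difference per site.
#'
#' @param hap A [simulate_haplotypes()] result or any list with elements
#'   `haplotypes` (h x L 0/1 matrix) and `locus_length`.
#' @return Per-site diversity (unitless, per bp).
#' @export
nucleotide_diversity <- function(hap) {
  h <- nrow(hap$haplotypes)
  if (h < 2L) stop("need at least 2 haplotypes")
  if (hap$locus_length <= 0) stop("locus_length must be > 0")
  j <- colSums(hap$haplotypes)
  sum(2 * j * (h - j) / (h * (h - 1))) / hap$locus_length
}

# Tajima (1989) sample-size constants for h sequences.
tajima_constants <- function(h) {
  a1 <- sum(1 / seq_len(h - 1))
  a2 <- sum(1 / seq_len(h - 1)^2)
  b1 <- (h + 1) / (3 * (h - 1))
  b2 <- 2 * (h^2 + h + 3) / (9 * h * (h - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (h + 2) / (a1 * h) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' Normalized difference between per-locus pairwise diversity and Watterson's
#' estimator: `D = (pi_total - S/a1) / sqrt(e1 S + e2 S (S - 1))` with the
#' standard sample-size constants. Approximately 0 under neutral
#' mutation-drift equilibrium; `S = 0` leaves it undefined (`NaN`).
#'
#' @param hap As for [nucleotide_diversity()].
#' @return List with `d` (`NaN` when undefined), `n_segregating`,
#'   `pi_total` (per-locus, not per-site).
#' @export
tajimas_d <- function(hap) {
  h <- nrow(hap$haplotypes)
  if (h < 2L) stop("need at least 2 haplotypes")
  s <- ncol(hap$haplotypes)
  j <- colSums(hap$haplotypes)
  pi_total <- sum(2 * j * (h - j) / (h * (h - 1)))
  if (s == 0L) {
    return(list(d = NaN, n_segregating = 0L, pi_total = pi_total))
  }
  k <- tajima_constants(h)
  d <- (pi_total - s / k$a1) / sqrt(k$e1 * s + k$e2 * s * (s - 1))
  list(d = d, n_segregating = s, pi_total = pi_total)
}

#' Per-gene diversity table
#'
#' Computes per-site nucleotide diversity and Tajima's D for a list of
#' per-gene haplotype alignments.
#'
#' @param haps Named list of haplotype alignments, one per gene.
#' @return Object of class `diversity_table`: a data frame with columns
#'   `gene_id`, `pi`, `tajima_d`, `n_segregating`.
#' @export
diversity_table <- function(haps) {
  rows <- lapply(names(haps), function(g) {
    td <- tajimas_d(haps[[g]])
    data.frame(gene_id = g,
               pi = nucleotide_diversity(haps[[g]]),
               tajima_d = td$d,
               n_segregating = td$n_segregating,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("diversity_table", class(out))
  out
}

#' Correlate gene degree with genetic diversity across datasets
#'
#' For each dataset (e.g. tissue-specific network), computes the Spearman
#' correlation between gene degree and a diversity statistic over the genes
#' shared by both tables, then pools the per-dataset correlations with a
#' DerSimonian-Laird random-effects meta-analysis on the Fisher-z scale.
#'
#' @param gene_degrees List of gene-axis `degree_vector` objects, one per
#'   dataset.
#' @param diversity A `diversity_table` (or data frame with `gene_id` plus
#'   the statistic column).
#' @param statistic `"pi"` or `"tajima_d"`.
#' @return List with `per_dataset` (data frame `dataset`, `rho`, `n`) and
#'   `meta` (a `meta_analysis_result`).
#' @export
correlate_degree_diversity <- function(gene_degrees, diversity,
                                       statistic = c("pi", "tajima_d")) {
  statistic <- match.arg(statistic)
  if (is.null(names(gene_degrees))) {
    names(gene_degrees) <- sprintf("dataset_%02d", seq_along(gene_degrees))
  }
  rows <- lapply(names(gene_degrees), function(ds) {
    tab <- gene_degrees[[ds]]$table
    shared <- intersect(tab$node_id, diversity$gene_id)
    if (length(shared) < 3L) stop(sprintf("dataset %s shares fewer than 3 genes", ds))
    d <- tab$total[match(shared, tab$node_id)]
    v <- diversity[[statistic]][match(shared, diversity$gene_id)]
    ok <- is.finite(v)
    data.frame(dataset = ds, rho = spearman_rho(d[ok], v[ok]), n = sum(ok),
               stringsAsFactors = FALSE)
  })
  per_dataset <- do.call(rbind, rows)
  meta <- random_effects_meta(per_dataset$rho, per_dataset$n)
  list(per_dataset = per_dataset, meta = meta)
}
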