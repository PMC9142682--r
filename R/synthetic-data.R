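#' Construct a genotype matrix object
#'
#' Container for biallelic SNP dosages with genomic coordinates and per-SNP
#' minor allele frequency. Rows are samples, columns are SNPs.
#'
#' @param dosages Numeric matrix, samples x SNPs, values in `[0, 2]`.
#' @param chrom Character vector of per-SNP chromosome labels.
#' @param pos Integer vector of 1-based SNP positions (bp), strictly
#'   increasing within each chromosome.
#' @param maf Optional per-SNP minor allele frequency; recomputed from the
#'   dosages when `NULL`.
#' @return An object of class `genotype_matrix` with elements `dosages`,
#'   `snp_ids`, `chrom`, `pos`, `maf`.
#' @export
genotype_matrix <- function(dosages, chrom, pos, maf = NULL) {
  dosages <- as.matrix(dosages)
  if (any(dosages < 0 | dosages > 2, na.rm = TRUE)) {
    stop("dosage values must lie in [0, 2]")
  }
  n_snps <- ncol(dosages)
  if (length(chrom) != n_snps || length(pos) != n_snps) {
    stop("`chrom` and `pos` must have one entry per SNP column")
  }
  if (is.null(colnames(dosages))) {
    colnames(dosages) <- sprintf("snp_%04d", seq_len(n_snps))
  }
  if (anyDuplicated(colnames(dosages))) stop("SNP ids must be unique")
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (length(p) > 1L && any(diff(p) <= 0)) {
      stop("positions must be strictly increasing within each chromosome")
    }
  }
  if (is.null(maf)) {
    af <- colMeans(dosages) / 2
    maf <- pmin(af, 1 - af)
  }
  structure(
    list(dosages = dosages, snp_ids = colnames(dosages),
         chrom = as.character(chrom), pos = as.integer(pos),
         maf = as.numeric(maf)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs on %d chromosome(s); MAF range [%.3f, %.3f]\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$chrom)),
              min(x$maf), max(x$maf)))
  invisible(x)
}

#' Construct an expression matrix object
#'
#' @param values Numeric matrix, samples x genes (normalized expression).
#' @param tss_chrom Per-gene chromosome of the transcription start site.
#' @param tss_pos Per-gene 1-based TSS position (bp).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, tss_chrom, tss_pos) {
  values <- as.matrix(values)
  m <- ncol(values)
  if (length(tss_chrom) != m || length(tss_pos) != m) {
    stop("`tss_chrom` and `tss_pos` must have one entry per gene column")
  }
  if (is.null(colnames(values))) colnames(values) <- sprintf("gene_%04d", seq_len(m))
  if (anyDuplicated(colnames(values))) stop("gene ids must be unique")
  if (anyNA(values)) stop("expression values must not contain missing entries")
  structure(
    list(values = values, gene_ids = colnames(values),
         tss_chrom = as.character(tss_chrom), tss_pos = as.integer(tss_pos)),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d samples x %d genes\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Simulate biallelic SNP dosages under Hardy-Weinberg equilibrium
#'
#' Each SNP draws a minor allele frequency uniformly from `maf_range`, then
#' each sample's dosage is the sum of two independent Bernoulli(maf) alleles,
#' giving hard calls in `{0, 1, 2}`. SNPs are laid out on chromosomes at a
#' fixed spacing so downstream cis/trans classification is well defined.
#'
#' @param n_samples Number of samples (rows), at least 2.
#' @param n_snps Total number of SNPs.
#' @param maf_range Length-2 numeric interval inside `[0.05, 0.5]`; a single
#'   value fixes the MAF for every SNP.
#' @param chrom_layout Optional data frame with columns `chrom`, `n_snps`,
#'   `spacing` (bp between consecutive SNPs). Default: SNPs split evenly over
#'   two chromosomes at 100 kb spacing.
#' @param seed Integer seed; results are bit-reproducible given the seed.
#' @return A [genotype_matrix()] whose `maf` slot holds the *empirical* minor
#'   allele frequency recomputed from the realized dosages.
#' @export
simulate_genotypes <- function(n_samples, n_snps,
                               maf_range = c(0.05, 0.5),
                               chrom_layout = NULL,
                               seed = 1L) {
  stopifnot_scalar_count(n_samples, "n_samples", min = 2L)
  stopifnot_scalar_count(n_snps, "n_snps", min = 1L)
  if (length(maf_range) == 1L) maf_range <- rep(maf_range, 2L)
  if (maf_range[1] > maf_range[2]) stop("degenerate maf_range: lower bound exceeds upper bound")
  if (maf_range[1] < 0.05 || maf_range[2] > 0.5) {
    stop("maf_range must lie within [0.05, 0.5]")
  }
  if (is.null(chrom_layout)) {
    n1 <- ceiling(n_snps / 2)
    chrom_layout <- data.frame(
      chrom = c("chr1", "chr2"),
      n_snps = c(n1, n_snps - n1),
      spacing = 1e5
    )
    chrom_layout <- chrom_layout[chrom_layout$n_snps > 0L, , drop = FALSE]
  }
  if (sum(chrom_layout$n_snps) != n_snps) {
    stop("chrom_layout SNP counts must sum to n_snps")
  }
  chrom <- rep(as.character(chrom_layout$chrom), chrom_layout$n_snps)
  pos <- unlist(lapply(seq_len(nrow(chrom_layout)), function(i) {
    seq_len(chrom_layout$n_snps[i]) * as.integer(chrom_layout$spacing[i])
  }), use.names = FALSE)

  with_seed(seed, {
    maf <- stats::runif(n_snps, maf_range[1], maf_range[2])
    a1 <- matrix(stats::rbinom(n_samples * n_snps, 1L, rep(maf, each = n_samples)),
                 nrow = n_samples)
    a2 <- matrix(stats::rbinom(n_samples * n_snps, 1L, rep(maf, each = n_samples)),
                 nrow = n_samples)
    dosages <- a1 + a2
    colnames(dosages) <- sprintf("snp_%04d", seq_len(n_snps))
    rownames(dosages) <- sprintf("sample_%04d", seq_len(n_samples))
    genotype_matrix(dosages, chrom = chrom, pos = pos)
  })
}

#' Simulate gene transcription start sites
#'
#' Places gene TSSs uniformly at random along the chromosomes spanned by a
#' genotype matrix (extending 1 Mb past the outermost SNPs so genes can sit
#' beyond the SNP grid).
#'
#' @param n_genes Number of genes.
#' @param geno A [genotype_matrix()] providing the chromosome layout.
#' @param seed Integer seed.
#' @return Data frame with columns `gene_id`, `chrom`, `tss`.
#' @export
simulate_genes <- function(n_genes, geno, seed = 1L) {
  stopifnot_scalar_count(n_genes, "n_genes", min = 1L)
  chroms <- unique(geno$chrom)
  with_seed(seed, {
    chrom <- sample(chroms, n_genes, replace = TRUE)
    tss <- integer(n_genes)
    for (ch in chroms) {
      idx <- which(chrom == ch)
      hi <- max(geno$pos[geno$chrom == ch]) + 1e6
      tss[idx] <- as.integer(stats::runif(length(idx), 1, hi))
    }
    ord <- order(match(chrom, chroms), tss)
    data.frame(gene_id = sprintf("gene_%04d", seq_len(n_genes)),
               chrom = chrom[ord], tss = tss[ord],
               stringsAsFactors = FALSE)
  })
}

#' Plant a sparse eQTL architecture
#'
#' Chooses cis edges among SNP-gene pairs within the cis window and trans
#' edges strictly across different chromosomes (so cis/trans labels are
#' unambiguous), each pair at most once.
#'
#' @param geno A [genotype_matrix()].
#' @param genes Gene table from [simulate_genes()].
#' @param n_cis,n_trans Number of cis and trans edges to plant.
#' @param beta_cis,beta_trans Effect sizes (expression units per allele);
#'   recycled over the respective edges.
#' @param noise_sd Residual standard deviation for expression (> 0).
#' @param covariate_effects Optional c x m matrix of covariate effects on the
#'   genes (`NULL` = none).
#' @param cis_window Window around the TSS defining cis pairs (bp).
#' @param seed Integer seed.
#' @return An object of class `planted_architecture` with elements
#'   `true_edges` (data frame: `snp`, `gene`, `beta`, `cis` with integer
#'   column indices), `noise_sd`, `covariate_effects`, `genes`.
#' @export
plant_architecture <- function(geno, genes, n_cis = 35L, n_trans = 15L,
                               beta_cis = 1, beta_trans = 1,
                               noise_sd = 1, covariate_effects = NULL,
                               cis_window = 1e6, seed = 1L) {
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  m <- nrow(genes)
  same_chrom <- outer(geno$chrom, genes$chrom, "==")
  dist <- abs(outer(geno$pos, genes$tss, "-"))
  cis_ok <- which(same_chrom & dist <= cis_window)
  trans_ok <- which(!same_chrom)
  if (length(cis_ok) < n_cis) stop("not enough eligible cis pairs")
  if (length(trans_ok) < n_trans) stop("not enough eligible trans (cross-chromosome) pairs")
  with_seed(seed, {
    pick_cis <- sample(cis_ok, n_cis)
    pick_trans <- sample(trans_ok, n_trans)
    idx <- c(pick_cis, pick_trans)
    n_snp <- length(geno$snp_ids)
    edges <- data.frame(
      snp = ((idx - 1L) %% n_snp) + 1L,
      gene = ((idx - 1L) %/% n_snp) + 1L,
      beta = c(rep_len(beta_cis, n_cis), rep_len(beta_trans, n_trans)),
      cis = rep(c(TRUE, FALSE), c(n_cis, n_trans))
    )
    if (anyDuplicated(edges[, c("snp", "gene")])) {
      edges <- edges[!duplicated(edges[, c("snp", "gene")]), , drop = FALSE]
    }
    structure(
      list(true_edges = edges, noise_sd = noise_sd,
           covariate_effects = covariate_effects, genes = genes),
      class = "planted_architecture"
    )
  })
}

#' Simulate a covariate matrix
#'
#' Generic standard-normal covariates standing in for genotype principal
#' components, sex, platform, and latent expression factors.
#'
#' @param n_samples Number of samples.
#' @param n_covariates Number of covariates.
#' @param seed Integer seed.
#' @return Numeric matrix samples x covariates with named columns.
#' @export
simulate_covariates <- function(n_samples, n_covariates, seed = 1L) {
  stopifnot_scalar_count(n_samples, "n_samples", min = 1L)
  stopifnot_scalar_count(n_covariates, "n_covariates", min = 0L)
  if (n_covariates == 0L) return(NULL)
  with_seed(seed, {
    x <- matrix(stats::rnorm(n_samples * n_covariates), nrow = n_samples)
    colnames(x) <- sprintf("cov_%02d", seq_len(n_covariates))
    x
  })
}

#' Simulate expression from a planted eQTL architecture
#'
#' Each gene is the sum of its planted dosage effects, covariate effects, and
#' i.i.d. Gaussian noise: `g_j = sum_i beta_ij s_i + X gamma_j + e`,
#' `e ~ N(0, noise_sd^2)`.
#'
#' @param geno A [genotype_matrix()].
#' @param arch A [plant_architecture()] result (supplies gene annotation,
#'   effect sizes, `noise_sd`, and covariate effects).
#' @param covariates Optional samples x c covariate matrix, same sample order
#'   as `geno`; required when `arch$covariate_effects` is non-NULL.
#' @param seed Integer seed.
#' @return An [expression_matrix()] paired sample-for-sample with `geno`.
#' @export
simulate_expression <- function(geno, arch, covariates = NULL, seed = 1L) {
  r <- nrow(geno$dosages)
  m <- nrow(arch$genes)
  edges <- arch$true_edges
  if (nrow(edges) > 0L &&
      (max(edges$snp) > ncol(geno$dosages) || max(edges$gene) > m)) {
    stop("planted edge references an out-of-range SNP or gene index")
  }
  with_seed(seed, {
    values <- matrix(stats::rnorm(r * m, sd = arch$noise_sd), nrow = r)
    if (nrow(edges) > 0L) {
      for (k in seq_len(nrow(edges))) {
        values[, edges$gene[k]] <- values[, edges$gene[k]] +
          edges$beta[k] * geno$dosages[, edges$snp[k]]
      }
    }
    if (!is.null(arch$covariate_effects)) {
      if (is.null(covariates)) stop("covariates required when arch has covariate effects")
      values <- values + covariates %*% arch$covariate_effects
    }
    colnames(values) <- arch$genes$gene_id
    rownames(values) <- rownames(geno$dosages)
    expression_matrix(values, tss_chrom = arch$genes$chrom, tss_pos = arch$genes$tss)
  })
}

#' Simulate neutral haplotypes under the Kingman coalescent
#'
#' Builds a coalescent genealogy for `n_haplotypes` lineages (exponential
#' waiting times with rate `k(k-1)/2` while `k` lineages remain) and drops
#' mutations on branches as a Poisson process with rate `theta/2` per unit
#' branch length, under the infinite-sites model (every mutation creates a
#' new polymorphic column). No recombination.
#'
#' @param n_haplotypes Number of sampled haplotypes, at least 2.
#' @param theta Population-scaled mutation rate for the whole locus (> 0).
#' @param locus_length Total locus length in bp (for per-site scaling of
#'   diversity); mutations receive distinct positions in `(0, locus_length]`.
#' @param seed Integer seed.
#' @return An object of class `haplotype_alignment`: `haplotypes` (h x L 0/1
#'   matrix), `locus_length`, `positions`, and `tmrca_events` (the number of
#'   coalescences, always `n_haplotypes - 1`).
#' @export
simulate_haplotypes <- function(n_haplotypes, theta, locus_length = 1e4, seed = 1L) {
  stopifnot_scalar_count(n_haplotypes, "n_haplotypes", min = 2L)
  if (!is.numeric(theta) || theta <= 0) stop("theta must be > 0")
  if (locus_length <= 0) stop("locus_length must be > 0")
  with_seed(seed, {
    # active lineages tracked as leaf index sets
    lineages <- lapply(seq_len(n_haplotypes), identity)
    cols <- list()
    n_coal <- 0L
    while (length(lineages) > 1L) {
      k <- length(lineages)
      t_k <- stats::rexp(1, rate = k * (k - 1) / 2)
      # mutations on each open branch during this interval
      n_mut <- stats::rpois(k, lambda = theta / 2 * t_k)
      for (i in which(n_mut > 0L)) {
        for (j in seq_len(n_mut[i])) {
          col <- integer(n_haplotypes)
          col[lineages[[i]]] <- 1L
          cols[[length(cols) + 1L]] <- col
        }
      }
      pair <- sample.int(k, 2L)
      merged <- c(lineages[[pair[1]]], lineages[[pair[2]]])
      lineages[[pair[1]]] <- merged
      lineages[[pair[2]]] <- NULL
      n_coal <- n_coal + 1L
    }
    s <- length(cols)
    hap <- if (s > 0L) do.call(cbind, cols) else matrix(0L, n_haplotypes, 0L)
    positions <- if (s > 0L) sort(stats::runif(s, 0, locus_length)) else numeric(0)
    structure(
      list(haplotypes = hap, locus_length = locus_length,
           positions = positions, tmrca_events = n_coal),
      class = "haplotype_alignment"
    )
  })
}

#' @export
print.haplotype_alignment <- function(x, ...) {
  cat(sprintf("haplotype_alignment: %d haplotypes, %d segregating sites, locus %g bp\n",
              nrow(x$haplotypes), ncol(x$haplotypes), x$locus_length))
  invisible(x)
}

#' Simulate GWAS chi-square statistics from an additive annotation model
#'
#' Draws each SNP's association statistic from a 1-df noncentral chi-square
#' whose mean follows the stratified heritability regression model
#' `E[chi^2_j] = N * sum_c l(j,c) tau_c + 1`, where the LD score
#' `l(j,c) = sum_k a_ck r^2_jk` (identity LD when `ld_r2` is `NULL`, i.e.
#' `l(j,c) = a_cj`). LD enters only through the mean; draws are independent
#' across SNPs.
#'
#' @param annotations SNP x annotation numeric matrix `a`.
#' @param tau Per-annotation coefficients (per-SNP heritability units).
#' @param N_gwas GWAS sample size.
#' @param ld_r2 Optional SNP x SNP squared-correlation matrix; `NULL` means
#'   no LD (identity).
#' @param seed Integer seed.
#' @return Data frame with columns `snp_id` (if annotation rows are named),
#'   `chisq`, and `e_chisq` (the model mean used as noncentrality + 1).
#' @export
simulate_gwas_chisq <- function(annotations, tau, N_gwas, ld_r2 = NULL, seed = 1L) {
  annotations <- as.matrix(annotations)
  if (ncol(annotations) != length(tau)) stop("length(tau) must equal ncol(annotations)")
  l <- if (is.null(ld_r2)) annotations else as.matrix(ld_r2) %*% annotations
  ncp <- as.numeric(N_gwas * (l %*% tau))
  if (any(ncp < 0)) stop("negative implied noncentrality: all E[chi^2] must be >= 1")
  with_seed(seed, {
    chisq <- stats::rchisq(length(ncp), df = 1, ncp = ncp)
    ids <- rownames(annotations)
    if (is.null(ids)) ids <- sprintf("snp_%04d", seq_along(ncp))
    data.frame(snp_id = ids, chisq = chisq, e_chisq = ncp + 1,
               stringsAsFactors = FALSE)
  })
}
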