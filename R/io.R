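#' Write genotypes as a minimal VCF
#'
#' CHROM, POS, ID, REF=A, ALT=G, QUAL=., FILTER=., INFO=., FORMAT=GT with
#' hard-call genotypes derived by rounding dosages.
#'
#' @param geno A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(geno, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(geno$dosages)), collapse = "\t")),
             con)
  gt_codes <- c("0/0", "0/1", "1/1")
  calls <- matrix(gt_codes[round(geno$dosages) + 1L], nrow = nrow(geno$dosages))
  for (j in seq_along(geno$snp_ids)) {
    writeLines(paste(c(geno$chrom[j], geno$pos[j], geno$snp_ids[j], "A", "G",
                       ".", ".", ".", "GT", calls[, j]), collapse = "\t"), con)
  }
  invisible(path)
}

# feature-by-sample TSV: first column = feature id, header = sample ids
write_feature_tsv <- function(mat_samples_by_features, feature_ids, path, id_col) {
  out <- data.frame(feature_ids, t(mat_samples_by_features),
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- c(id_col, rownames(mat_samples_by_features))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a dosage matrix as TSV (SNPs x samples)
#' @param geno A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(geno, path) {
  write_feature_tsv(geno$dosages, geno$snp_ids, path, "snp_id")
}

#' Write an expression matrix as TSV (genes x samples)
#' @param expr An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  write_feature_tsv(expr$values, expr$gene_ids, path, "gene_id")
}

#' Write gene TSS as 4-column BED
#'
#' BED is half-open and 0-based: each TSS at 1-based position `t` is written
#' as `(chrom, t-1, t, gene_id)`.
#'
#' @param genes Gene table with `gene_id`, `chrom`, `tss`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(genes, path) {
  bed <- data.frame(genes$chrom, genes$tss - 1L, genes$tss, genes$gene_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 4-column TSS BED back to a gene table
#' @param path BED file path (chrom, start, end, gene_id; 0-based half-open).
#' @return Data frame `gene_id`, `chrom`, `tss` (1-based).
#' @export
read_gene_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "gene_id"),
                           stringsAsFactors = FALSE)
  data.frame(gene_id = bed$gene_id, chrom = bed$chrom,
             tss = bed$end, stringsAsFactors = FALSE)
}

#' Write a degree vector as TSV
#' @param deg A `degree_vector`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_degree_tsv <- function(deg, path) {
  out <- cbind(deg$table[, "node_id", drop = FALSE],
               axis = deg$axis,
               deg$table[, c("total", "cis_part", "trans_part")])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an annotation vector as 2-column TSV
#' @param ann An `annotation_vector`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(ann, path) {
  utils::write.table(data.frame(snp_id = ann$snp_ids, value = ann$value),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
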