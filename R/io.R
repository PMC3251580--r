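#' Read a genotype matrix from TSV
#'
#' The file has a header line `sample_id` followed by SNP identifiers; each
#' subsequent row holds one sample's additive dosages (0/1/2, `NA` for
#' missing calls).
#'
#' @param path Path to a tab-separated genotype file.
#' @return Numeric matrix (samples x SNPs) with sample ids as rownames and
#'   SNP ids as colnames.
#' @export
read_genotypes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = NA)
  if (names(df)[1] != "sample_id") {
    stop("genotype file must start with a 'sample_id' column: ", path)
  }
  g <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(g) <- "double"
  rownames(g) <- as.character(df$sample_id)
  bad <- g[!is.na(g) & !(g %in% c(0, 1, 2))]
  if (length(bad)) {
    stop("genotype dosages must be 0/1/2/NA; found e.g. ", bad[1])
  }
  g
}

#' Write a genotype matrix to TSV
#'
#' @param genotypes Numeric samples x SNPs matrix with dimnames.
#' @param path Output path.
#' @export
write_genotypes <- function(genotypes, path) {
  df <- data.frame(sample_id = rownames(genotypes),
                   genotypes, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the per-sample outcome and covariate table
#'
#' Columns: `sample_id`, `status` (0 control / 1 case), `age`, `sex` (0/1),
#' `study`, `dna_source` (0/1), `smoking`
#' (never/former/occasional/current).
#'
#' @param path Path to a tab-separated sample table.
#' @return data.frame with `study` and `smoking` as factors (smoking
#'   reference level "never").
#' @export
read_samples <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(sample_id = "character"))
  validate_samples(df)
}

#' @keywords internal
validate_samples <- function(df) {
  need <- c("sample_id", "status", "age", "sex", "study", "dna_source",
            "smoking")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyNA(df[need])) stop("sample table has missing values; covariate ",
                            "missingness is not supported")
  if (!all(df$status %in% c(0, 1))) stop("status must be 0/1")
  smoking_levels <- c("never", "former", "occasional", "current")
  if (!all(df$smoking %in% smoking_levels)) {
    stop("smoking must be one of: ", paste(smoking_levels, collapse = ", "))
  }
  df$smoking <- factor(df$smoking, levels = smoking_levels)
  df$study <- factor(df$study)
  df
}

#' Write a sample table to TSV
#' @param samples data.frame as returned by [read_samples()].
#' @param path Output path.
#' @export
write_samples <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a SNP coordinate table
#'
#' Columns: `snp_id`, `chrom`, `pos` (1-based), `allele_a`, `allele_b`.
#'
#' @param path Path to a tab-separated SNP table.
#' @return data.frame.
#' @export
read_snp_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(snp_id = "character",
                                         chrom = "character"))
  need <- c("snp_id", "chrom", "pos")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("SNP table lacks columns: ",
                         paste(miss, collapse = ", "))
  df
}

#' @rdname read_snp_table
#' @param snps SNP table data.frame.
#' @export
write_snp_table <- function(snps, path) {
  utils::write.table(snps, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene coding regions from a BED file
#'
#' BED uses 0-based half-open coordinates; internally genes are held 1-based
#' inclusive (`start = bed_start + 1`, `end = bed_end`). Expected columns:
#' chrom, start, end, gene_id, score, strand.
#'
#' @param path Path to a 6-column BED file (no header).
#' @return data.frame with columns `gene_id, chrom, start, end, strand` in
#'   1-based inclusive coordinates.
#' @export
read_gene_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, check.names = FALSE,
                          colClasses = c("character", "integer", "integer",
                                         "character", "character",
                                         "character"))
  if (ncol(df) < 6) stop("gene BED needs 6 columns (chrom start end name ",
                         "score strand): ", path)
  names(df)[1:6] <- c("chrom", "bed_start", "bed_end", "gene_id", "score",
                      "strand")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  out <- data.frame(gene_id = df$gene_id, chrom = df$chrom,
                    start = df$bed_start + 1L, end = df$bed_end,
                    strand = df$strand, stringsAsFactors = FALSE)
  if (any(out$start > out$end)) stop("gene with start > end in ", path)
  out
}

#' Write gene models to BED (0-based half-open)
#' @param genes data.frame with `gene_id, chrom, start, end, strand`
#'   (1-based inclusive).
#' @param path Output path.
#' @export
write_gene_bed <- function(genes, path) {
  bed <- data.frame(genes$chrom, genes$start - 1L, genes$end, genes$gene_id,
                    0L, genes$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a pathway database to GMT
#' @param db A `pathway_db` object.
#' @param path Output path.
#' @export
write_gmt <- function(db, path) {
  stopifnot(inherits(db, "pathway_db"))
  lines <- vapply(names(db$sets), function(id) {
    paste(c(id, db$source[[id]], db$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
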