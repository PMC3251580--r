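#' Load gene sets from a GMT file
#'
#' GMT lines are `set_id<TAB>source<TAB>gene1<TAB>gene2...`. Duplicate genes
#' within a set are dropped with a warning; a line with fewer than three
#' fields is a parse error reported with its line number.
#'
#' @param gmt_path Path to a GMT file.
#' @return A `pathway_db` object: list with `sets` (named list of gene-id
#'   character vectors) and `source` (named character vector of source
#'   labels).
#' @export
load_gene_sets <- function(gmt_path) {
  lines <- readLines(gmt_path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", gmt_path)
    return(pathway_db(list(), character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short)) {
    stop("malformed GMT line ", short[1], " (fewer than 3 fields) in ",
         gmt_path)
  }
  ids <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(ids)) {
    stop("duplicate set ids in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  src <- vapply(fields, `[[`, character(1), 2)
  sets <- lapply(fields, function(f) f[-(1:2)])
  ndup <- sum(vapply(sets, anyDuplicated, integer(1)) > 0)
  if (ndup) {
    warning(ndup, " set(s) listed a gene more than once; duplicates dropped")
    sets <- lapply(sets, unique)
  }
  names(sets) <- ids
  names(src) <- ids
  pathway_db(sets, src)
}

#' Construct a pathway database object
#' @param sets Named list of character vectors of gene ids.
#' @param source Named character vector of source labels, same names.
#' @return A `pathway_db`.
#' @export
pathway_db <- function(sets, source = setNames(rep("Self", length(sets)),
                                               names(sets))) {
  stopifnot(identical(names(sets), names(source)) || !length(sets))
  structure(list(sets = sets, source = source), class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat("pathway_db:", length(x$sets), "sets")
  if (length(sizes)) cat(", sizes", min(sizes), "-", max(sizes))
  cat("\n")
  invisible(x)
}

#' Filter pathways by size
#'
#' Retains sets whose gene count lies within `[min_genes, max_genes]`
#' (bounds inclusive); the default 5-100 window avoids testing too
#' narrowly or too broadly defined functional categories.
#'
#' @param db A `pathway_db`.
#' @param min_genes,max_genes Inclusive size bounds.
#' @return Filtered `pathway_db`.
#' @export
filter_pathways <- function(db, min_genes = 5, max_genes = 100) {
  stopifnot(inherits(db, "pathway_db"))
  if (min_genes > max_genes) stop("min_genes > max_genes")
  sizes <- lengths(db$sets)
  keep <- sizes >= min_genes & sizes <= max_genes
  if (!any(keep) && length(db$sets)) {
    warning("all pathways removed by the size filter")
  }
  pathway_db(db$sets[keep], db$source[keep])
}

#' Map SNPs to genes with strand-aware flanking regions
#'
#' A SNP is assigned to every gene whose extended region contains it. For a
#' `+` strand gene the region is `[start - upstream, end + downstream]`; for
#' a `-` strand gene, `[start - downstream, end + upstream]` (the 5' flank
#' is on the high-coordinate side). Bounds are inclusive, 1-based.
#'
#' @param snps SNP table (`snp_id, chrom, pos`).
#' @param genes Gene models (`gene_id, chrom, start, end, strand`, 1-based
#'   inclusive, as from [read_gene_bed()]).
#' @param upstream,downstream Flank sizes in bp (defaults 20 kb 5' and
#'   10 kb 3').
#' @return A `snp_gene_map`: list with `snp2gene` and `gene2snp` (named
#'   lists of character vectors, exact inverses of one another).
#' @export
map_snps_to_genes <- function(snps, genes, upstream = 20000,
                              downstream = 10000) {
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'")
  }
  known <- snps$chrom %in% unique(genes$chrom)
  if (!all(known)) {
    warning(sum(!known), " SNP(s) on chromosomes absent from the gene ",
            "table were skipped")
    snps <- snps[known, , drop = FALSE]
  }
  plus <- genes$strand == "+"
  reg_start <- ifelse(plus, genes$start - upstream, genes$start - downstream)
  reg_end <- ifelse(plus, genes$end + downstream, genes$end + upstream)
  gene_gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = pmax(reg_start, 1L), end = reg_end))
  snp_gr <- GenomicRanges::GRanges(
    seqnames = snps$chrom,
    ranges = IRanges::IRanges(start = snps$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(snp_gr, gene_gr)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  snp2gene <- lapply(split(genes$gene_id[si], snps$snp_id[qi]),
                     function(g) sort(unique(g)))
  gene2snp <- lapply(split(snps$snp_id[qi], genes$gene_id[si]),
                     function(s) sort(unique(s)))
  snp_gene_map(snp2gene, gene2snp)
}

#' @keywords internal
snp_gene_map <- function(snp2gene, gene2snp) {
  structure(list(snp2gene = snp2gene, gene2snp = gene2snp),
            class = "snp_gene_map")
}

#' @export
print.snp_gene_map <- function(x, ...) {
  cat("snp_gene_map:", length(x$snp2gene), "SNPs ->",
      length(x$gene2snp), "genes\n")
  invisible(x)
}

#' Percentage of overlapping genes between two pathways
#'
#' Computed as `100 * |A intersect B| / d` where the denominator `d` is, by
#' convention, `min(N_A, N_B)` (keeps nested sets at 100%); `union` and
#' `mean` denominators are available.
#'
#' @param db A `pathway_db`.
#' @param id_a,id_b Set ids.
#' @param denominator One of "min", "union", "mean".
#' @return Percentage in \[0, 100\].
#' @export
pathway_overlap <- function(db, id_a, id_b,
                            denominator = c("min", "union", "mean")) {
  denominator <- match.arg(denominator)
  for (id in c(id_a, id_b)) {
    if (!id %in% names(db$sets)) stop("unknown pathway id: ", id)
  }
  a <- db$sets[[id_a]]
  b <- db$sets[[id_b]]
  shared <- length(intersect(a, b))
  d <- switch(denominator,
              min = min(length(a), length(b)),
              union = length(union(a, b)),
              mean = (length(a) + length(b)) / 2)
  100 * shared / d
}

#' Pool genes that share mapped SNPs into locus units
#'
#' Genes tagged by the same SNPs carry redundant association evidence;
#' treating each as an independent pathway member double-counts one signal.
#' Union-find over genes: two genes join one unit iff they share at least
#' one mapped SNP, transitively closed; a unit's SNP set is the union of its
#' members' SNPs.
#'
#' @param map A `snp_gene_map`.
#' @param pathway_genes Optional character vector restricting pooling to
#'   these genes (e.g. one pathway's members). Default: all mapped genes.
#' @return A `locus_units` object: list with `units` (named list unit_id ->
#'   member gene ids), `gene2unit` (named character), `unit2snp` (named list
#'   unit_id -> snp ids).
#' @export
pool_shared_loci <- function(map, pathway_genes = NULL) {
  stopifnot(inherits(map, "snp_gene_map"))
  genes <- names(map$gene2snp)
  if (!is.null(pathway_genes)) genes <- intersect(genes, pathway_genes)
  genes <- sort(genes)
  parent <- seq_along(genes)
  names(parent) <- genes
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  idx <- match(genes, genes)
  names(idx) <- genes
  for (snp in names(map$snp2gene)) {
    gs <- intersect(map$snp2gene[[snp]], genes)
    if (length(gs) > 1) {
      roots <- vapply(match(gs, genes), find, integer(1))
      r0 <- min(roots)
      for (r in roots) parent[r] <- r0
    }
  }
  root <- vapply(seq_along(genes), find, integer(1))
  units <- split(genes, root)
  # unit id: lexicographically first member gene
  names(units) <- vapply(units, `[[`, character(1), 1)
  units <- units[order(names(units))]
  gene2unit <- stats::setNames(rep(names(units), lengths(units)),
                               unlist(units))
  unit2snp <- lapply(units, function(members) {
    sort(unique(unlist(map$gene2snp[members], use.names = FALSE)))
  })
  structure(list(units = units, gene2unit = gene2unit,
                 unit2snp = unit2snp),
            class = "locus_units")
}

#' @export
print.locus_units <- function(x, ...) {
  cat("locus_units:", length(x$units), "units over",
      length(x$gene2unit), "genes\n")
  invisible(x)
}

#' Drop pathway genes without coordinates or mapped SNPs
#'
#' @param db A `pathway_db`.
#' @param keep_genes Character vector of genes with usable data.
#' @return Filtered `pathway_db` (sets may shrink; empty sets removed), with
#'   a message reporting how many gene memberships were dropped.
#' @export
restrict_db_to_genes <- function(db, keep_genes) {
  stopifnot(inherits(db, "pathway_db"))
  before <- sum(lengths(db$sets))
  sets <- lapply(db$sets, intersect, keep_genes)
  dropped <- before - sum(lengths(sets))
  if (dropped > 0) {
    message(dropped, " pathway gene membership(s) dropped (no mapped data)")
  }
  keep <- lengths(sets) > 0
  pathway_db(sets[keep], db$source[keep])
}
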