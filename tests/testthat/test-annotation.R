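write_tmp_gmt <- function(lines) {
  f <- withr::local_tempfile(fileext = ".gmt",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("GMT loading parses sets, dedups genes, rejects malformed lines", {
  f <- write_tmp_gmt(c("setA\tKEGG\tg1\tg2\tg3",
                       "setB\tReactome\tg2\tg4",
                       "setC\tSelf\tg5\tg5\tg6"))
  expect_warning(db <- load_gene_sets(f), "duplicates dropped")
  expect_length(db$sets, 3)
  expect_equal(db$source[["setB"]], "Reactome")
  expect_equal(length(db$sets$setC), 2)   # duplicate counted once

  f2 <- write_tmp_gmt(c("setA\tKEGG\tg1", "broken\tonlyone"))
  expect_error(load_gene_sets(f2), "line 2")

  f3 <- write_tmp_gmt(character(0))
  expect_warning(db3 <- load_gene_sets(f3), "empty")
  expect_length(db3$sets, 0)
})

test_that("pathway size filter is inclusive on both bounds", {
  sets <- list(a = paste0("g", 1:4), b = paste0("g", 1:5),
               c = paste0("g", 1:100), d = paste0("g", 1:101))
  db <- pathway_db(sets)
  kept <- filter_pathways(db, 5, 100)
  expect_setequal(names(kept$sets), c("b", "c"))
  expect_equal(names(filter_pathways(db, 1, Inf)$sets), names(sets))
  expect_warning(empty <- filter_pathways(db, 200, 300), "all pathways")
  expect_length(empty$sets, 0)
  expect_error(filter_pathways(db, 10, 5), "min_genes")
})

test_that("SNP-gene mapping applies the strand-aware 20kb/10kb rule", {
  genes <- data.frame(gene_id = c("gp", "gm"), chrom = "chr1",
                      start = c(100000, 100000), end = c(120000, 120000),
                      strand = c("+", "-"))
  snps <- data.frame(snp_id = sprintf("s%d", 1:8), chrom = "chr1",
                     pos = c(80000, 79999, 130000, 130001,
                             140000, 140001, 90000, 89999))
  m_plus <- map_snps_to_genes(snps, genes[1, ])
  expect_true("s1" %in% names(m_plus$snp2gene))   # start - 20000 inclusive
  expect_false("s2" %in% names(m_plus$snp2gene))
  expect_true("s3" %in% names(m_plus$snp2gene))   # end + 10000 inclusive
  expect_false("s4" %in% names(m_plus$snp2gene))
  m_minus <- map_snps_to_genes(snps, genes[2, ])
  expect_true("s5" %in% names(m_minus$snp2gene))  # 5' flank on high side
  expect_false("s6" %in% names(m_minus$snp2gene))
  expect_true("s7" %in% names(m_minus$snp2gene))  # 3' flank 10 kb low side
  expect_false("s8" %in% names(m_minus$snp2gene))
})

test_that("a SNP inside two overlapping regions maps to both genes", {
  genes <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                      start = c(100, 150), end = c(200, 260),
                      strand = "+")
  snps <- data.frame(snp_id = "s1", chrom = "chr1", pos = 180)
  m <- map_snps_to_genes(snps, genes, upstream = 10, downstream = 10)
  expect_setequal(m$snp2gene$s1, c("a", "b"))
  expect_equal(m$gene2snp$a, "s1")
  expect_equal(m$gene2snp$b, "s1")
})

test_that("mapping warns on unknown chromosomes and ignores row order", {
  genes <- data.frame(gene_id = "a", chrom = "chr1", start = 1000,
                      end = 2000, strand = "+")
  snps <- data.frame(snp_id = c("s1", "s2"), chrom = c("chr1", "chrX"),
                     pos = c(1500, 1500))
  expect_warning(m1 <- map_snps_to_genes(snps, genes), "skipped")
  m2 <- suppressWarnings(map_snps_to_genes(snps[2:1, ], genes))
  expect_identical(m1$snp2gene, m2$snp2gene)
  expect_identical(m1$gene2snp, m2$gene2snp)
})

test_that("pathway overlap follows the chosen denominator and is symmetric", {
  db <- pathway_db(list(A = paste0("g", 1:10), B = paste0("g", 6:25),
                        C = paste0("h", 1:4)))
  expect_equal(pathway_overlap(db, "A", "A"), 100)
  expect_equal(pathway_overlap(db, "A", "C"), 0)
  expect_equal(pathway_overlap(db, "A", "B"), 50)          # 5 / min(10,20)
  expect_equal(pathway_overlap(db, "B", "A"), 50)
  expect_equal(pathway_overlap(db, "A", "B", "union"), 20) # 5 / 25
  expect_equal(pathway_overlap(db, "A", "B", "mean"), 100 * 5 / 15)
  expect_error(pathway_overlap(db, "A", "nope"), "unknown")
})

test_that("locus pooling is transitive and partitions the genes", {
  map <- pathgwas:::snp_gene_map(
    list(s1 = c("A", "B"), s2 = c("B", "C"), s3 = "D"),
    list(A = "s1", B = c("s1", "s2"), C = "s2", D = "s3"))
  u <- pool_shared_loci(map)
  expect_length(u$units, 2)
  expect_setequal(u$units[["A"]], c("A", "B", "C"))
  expect_setequal(u$unit2snp[["A"]], c("s1", "s2"))
  # partition: each gene in exactly one unit, sizes sum to gene count
  expect_equal(sum(lengths(u$units)), 4)
  expect_setequal(unlist(u$units), c("A", "B", "C", "D"))

  solo <- pathgwas:::snp_gene_map(list(s1 = "A", s2 = "B"),
                                  list(A = "s1", B = "s2"))
  expect_length(pool_shared_loci(solo)$units, 2)
})

test_that("BED round trip preserves 1-based inclusive gene models", {
  genes <- data.frame(gene_id = c("a", "b"), chrom = c("chr1", "chr2"),
                      start = c(100000, 5000), end = c(120000, 9000),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".bed")
  write_gene_bed(genes, f)
  bed <- utils::read.delim(f, header = FALSE)
  expect_equal(bed$V2, genes$start - 1L)   # 0-based on disk
  back <- read_gene_bed(f)
  expect_equal(back[, c("gene_id", "chrom", "start", "end", "strand")],
               genes)
})
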