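small_cfg <- function(...) {
  sim_config(n_studies = 2, n_cases = 60, n_controls = 60, n_snps = 40,
             block_size = 4, n_pathways = 5, pathway_size_range = c(3, 6),
             seed = 11, ...)
}

test_that("config validation rejects impossible settings", {
  expect_error(small_cfg(block_size = 100), "block_size")
  expect_error(small_cfg(maf_range = c(0.001, 0.5)), "maf_range")
  expect_error(small_cfg(causal = list(list(pathway = 1, n_causal_genes = 1,
                                            log_or = c(0.1, 0.2, 0.3)))),
               "log_or")
})

test_that("genotypes are 0/1/2 dosages with near-independent blocks at rho 0", {
  cfg <- sim_config(n_studies = 1, n_cases = 10, n_controls = 10,
                    n_snps = 12, block_size = 4, within_block_rho = 0,
                    maf_range = c(0.2, 0.4), n_pathways = 0, seed = 3)
  g <- simulate_genotypes(cfg, n_total = 5000)$genotypes
  expect_true(all(g %in% c(0, 1, 2)))
  cc <- stats::cor(g)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)
})

test_that("within-block LD is present at high rho and absent across blocks", {
  cfg <- sim_config(n_studies = 1, n_cases = 10, n_controls = 10,
                    n_snps = 8, block_size = 4, within_block_rho = 0.9,
                    maf_range = c(0.2, 0.4), n_pathways = 0, seed = 4)
  g <- simulate_genotypes(cfg, n_total = 4000)$genotypes
  cc <- stats::cor(g)
  expect_gt(cc[1, 2], 0.4)            # adjacent, same block
  expect_lt(abs(cc[1, 5]), 0.06)      # different blocks
})

test_that("empirical MAF tracks the drawn MAF within sampling error", {
  cfg <- sim_config(n_studies = 1, n_cases = 10, n_controls = 10,
                    n_snps = 10, block_size = 5, within_block_rho = 0.5,
                    maf_range = c(0.3, 0.3), n_pathways = 0, seed = 5)
  sim <- simulate_genotypes(cfg, n_total = 5000)
  emp <- colMeans(sim$genotypes) / 2
  expect_true(all(abs(emp - 0.3) < 0.02))
})

test_that("the gene layout reproduces the intended SNP-gene assignment", {
  cfg <- small_cfg()
  sim <- simulate_genotypes(cfg, n_total = 50)
  map <- map_snps_to_genes(sim$snps, sim$genes)
  expect_identical(
    vapply(map$snp2gene[names(sim$gene_of_snp)], paste, character(1),
           collapse = ","),
    stats::setNames(unname(sim$gene_of_snp), names(sim$gene_of_snp)))
})

test_that("phenotype simulation meets per-study quotas and labels truth", {
  cfg <- small_cfg(causal = list(list(pathway = 1, n_causal_genes = 2,
                                      log_or = c(0.3, -0.3))))
  ds <- simulate_dataset(cfg)
  tab <- table(ds$samples$study, ds$samples$status)
  expect_true(all(tab[, "1"] == 60) && all(tab[, "0"] == 60))
  expect_equal(nrow(ds$truth$causal_snps), 2)
  expect_setequal(ds$truth$heterogeneous_snps, ds$truth$causal_snps$snp_id)
  expect_equal(ds$truth$enriched_pathways, "pw0001")
  # every causal SNP maps into a gene of the enriched pathway
  expect_true(all(ds$truth$causal_snps$gene_id %in%
                    ds$db$sets[["pw0001"]]))
})

test_that("an undersized cohort fails with advice to raise the multiplier", {
  cfg <- small_cfg(study_intercepts = c(-6, -6), cohort_multiplier = 1.1)
  expect_error(simulate_dataset(cfg), "cohort_multiplier")
})

test_that("datasets round-trip through the on-disk formats", {
  cfg <- small_cfg()
  ds <- simulate_dataset(cfg)
  d1 <- withr::local_tempdir()
  write_dataset(ds, d1)
  expect_length(readLines(file.path(d1, "pathways.gmt")), 5)
  back <- suppressWarnings(read_dataset(d1))
  expect_equal(back$genotypes, ds$genotypes)
  expect_equal(back$samples, ds$samples)
  expect_equal(back$snps, ds$snps)
  expect_equal(back$genes,
               ds$genes[, c("gene_id", "chrom", "start", "end", "strand")],
               ignore_attr = TRUE)
  expect_equal(back$db$sets, ds$db$sets)
  expect_true(all(back$genotypes %in% c(0, 1, 2, NA)))
})

test_that("the same seed reproduces byte-identical dataset files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_dataset(simulate_dataset(small_cfg()), d1)
  write_dataset(simulate_dataset(small_cfg()), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("dataset writing validates id consistency across tables", {
  ds <- simulate_dataset(small_cfg())
  colnames(ds$genotypes)[1] <- "rogue_snp"
  expect_error(write_dataset(ds, withr::local_tempdir()), "rogue_snp")
})

test_that("under the global null trend-test p-values are uniform", {
  cfg <- sim_config(n_studies = 1, n_cases = 400, n_controls = 400,
                    n_snps = 2000, block_size = 4, within_block_rho = 0,
                    maf_range = c(0.05, 0.5), n_pathways = 0,
                    cohort_multiplier = 3, seed = 17)
  ds <- simulate_dataset(cfg)
  res <- assoc_scan(ds$genotypes, ds$samples,
                    covariates = c("age", "sex", "smoking", "dna_source"))
  p <- res$p_trend[!res$excluded]
  expect_gt(length(p), 1900)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a single causal SNP's OR is recovered across seeds", {
  hits <- 0L
  for (s in 1:20) {
    cfg <- sim_config(n_studies = 1, n_cases = 2000, n_controls = 2000,
                      n_snps = 15, block_size = 5, within_block_rho = 0.3,
                      maf_range = c(0.2, 0.4), n_pathways = 1,
                      pathway_size_range = c(2, 2), cohort_multiplier = 3,
                      causal = list(list(pathway = 1, n_causal_genes = 1,
                                         log_or = log(1.5))),
                      seed = 100 + s)
    ds <- simulate_dataset(cfg)
    snp <- ds$truth$causal_snps$snp_id[1]
    tt <- trend_test(ds$genotypes[, snp][ds$samples$sample_id], ds$samples,
                     covariates = c("age", "sex", "smoking", "dna_source"))
    if (!tt$excluded && tt$or_ >= 1.3 && tt$or_ <= 1.7) hits <- hits + 1L
  }
  expect_gte(hits, 18)   # >= 90% of 20 seeds
})
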