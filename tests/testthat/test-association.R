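test_that("control MAF is complete-case, pooled, and folded", {
  g <- cbind(s1 = c(0, 0, 1, 1, 2, 2), s2 = c(2, 2, 2, 1, 0, 0),
             s3 = c(2, 2, 2, 2, NA, 1), s4 = c(NA, NA, NA, NA, 0, 1))
  rownames(g) <- sprintf("i%04d", 1:6)
  sam <- make_samples(status = c(0, 0, 0, 0, 1, 1))
  expect_equal(control_maf(g, sam, "s1"), 0.25)
  expect_equal(control_maf(g, sam, "s2"), 0.125)   # 7/8 major -> folded
  expect_equal(control_maf(g, sam, "s3"), 0)       # all dosage 2 -> folded
  expect_warning(m <- control_maf(g, sam, "s4"), "no non-missing")
  expect_true(is.na(m))
})

test_that("a balanced table gives OR 1 and p near 1", {
  g <- c(rep(1, 50), rep(0, 50), rep(1, 50), rep(0, 50))
  sam <- make_samples(status = rep(c(1, 0), each = 100))
  tt <- trend_test(g, sam, covariates = character(0))
  expect_false(tt$excluded)
  expect_equal(tt$or_, 1, tolerance = 1e-8)
  expect_equal(tt$p_trend, 1, tolerance = 1e-6)
  expect_equal(tt$ci_low, exp(tt$beta - 1.96 * tt$se))
  expect_equal(tt$ci_high, exp(tt$beta + 1.96 * tt$se))
})

test_that("degenerate dosages and separation are flagged, not fitted", {
  sam <- make_samples(status = rep(c(1, 0), each = 20))
  tt <- trend_test(rep(1, 40), sam, covariates = character(0))
  expect_true(tt$excluded)
  expect_match(tt$reason, "constant")
  sep <- c(rep(2, 20), rep(0, 20))   # dosage separates cases from controls
  tt2 <- trend_test(sep, sam, covariates = character(0))
  expect_true(tt2$excluded)
  expect_match(tt2$reason, "separation")
})

test_that("missing genotypes are dropped per SNP (complete-case)", {
  set.seed(1)
  g <- rbinom(200, 2, 0.3)
  g[1:10] <- NA
  sam <- make_samples(status = rep(c(1, 0), 100))
  tt <- trend_test(g, sam, covariates = character(0))
  expect_equal(tt$n_used, 190)
})

test_that("the Wald fit agrees with a likelihood-ratio fit in -log10 p", {
  set.seed(7)
  for (i in 1:15) {
    n <- 1000
    g <- rbinom(n, 2, runif(1, 0.15, 0.5))
    b <- runif(1, -0.3, 0.3)
    y <- rbinom(n, 1, plogis(-0.3 + b * g))
    sam <- make_samples(status = y)
    tt <- trend_test(g, sam, covariates = character(0))
    if (tt$excluded) next
    f1 <- stats::glm(y ~ g, family = binomial())
    f0 <- stats::glm(y ~ 1, family = binomial())
    p_lrt <- stats::pchisq(f0$deviance - f1$deviance, 1, lower.tail = FALSE)
    expect_lt(abs(log10(tt$p_trend) - log10(p_lrt)), 0.2)
  }
})

test_that("a covariate independent of outcome and dosage barely moves beta", {
  set.seed(11)
  n <- 10000
  g <- rbinom(n, 2, 0.3)
  y <- rbinom(n, 1, plogis(-0.5 + 0.2 * g))
  sam <- make_samples(status = y, age = rnorm(n))
  b0 <- trend_test(g, sam, covariates = character(0))$beta
  b1 <- trend_test(g, sam, covariates = "age")$beta
  expect_lt(abs(b0 - b1), 1e-2)
})

test_that("the control-MAF filter is strict at 1%", {
  n_ctl <- 1000
  g_rare <- c(rep(1, 18), rep(0, n_ctl - 18), rbinom(200, 2, 0.3))
  g_edge <- c(rep(1, 20), rep(0, n_ctl - 20), rbinom(200, 2, 0.3))
  g <- cbind(rare = g_rare, edge = g_edge)
  rownames(g) <- sprintf("i%04d", 1:1200)
  sam <- make_samples(status = c(rep(0, n_ctl), rep(1, 200)))
  res <- assoc_scan(g, sam, covariates = character(0))
  expect_true(res$excluded[res$snp_id == "rare"])    # MAF 0.009 < 0.01
  expect_false(res$excluded[res$snp_id == "edge"])   # MAF 0.010, retained
})

test_that("best-SNP reduction takes the minimum with deterministic ties", {
  map <- pathgwas:::snp_gene_map(
    list(s1 = "gA", s2 = "gA", s3 = "gA", s4 = "gB", s5 = "gB"),
    list(gA = c("s1", "s2", "s3"), gB = c("s4", "s5")))
  res <- data.frame(snp_id = c("s3", "s1", "s2", "s5", "s4"),
                    p_trend = c(0.2, 0.4, 0.01, 0.07, 0.07),
                    excluded = FALSE)
  gr <- best_snp_per_gene(map, res)
  a <- gr[gr$gene_id == "gA", ]
  expect_equal(a$p_j, 0.01)
  expect_equal(a$r_j, 2)
  expect_equal(a$best_snp_id, "s2")
  expect_equal(a$snp_rank, 1L)
  b <- gr[gr$gene_id == "gB", ]
  expect_equal(b$best_snp_id, "s4")   # tie -> lexicographically smaller id
  # invariant to input row order
  gr2 <- best_snp_per_gene(map, res[sample(5), ])
  expect_equal(gr, gr2, ignore_attr = TRUE)
})

test_that("excluded SNPs still count for the reported SNP rank", {
  map <- pathgwas:::snp_gene_map(list(s1 = "gA", s2 = "gA"),
                                 list(gA = c("s1", "s2")))
  res <- data.frame(snp_id = c("s1", "s2"), p_trend = c(0.001, 0.01),
                    excluded = FALSE)
  gr <- best_snp_per_gene(map, res, drop_snps = "s1")
  expect_equal(gr$best_snp_id, "s2")
  expect_equal(gr$snp_rank, 2L)
})

test_that("pooled locus units score at most their members' p-values", {
  map <- pathgwas:::snp_gene_map(
    list(s1 = c("gA", "gB"), s2 = "gA", s3 = "gB"),
    list(gA = c("s1", "s2"), gB = c("s1", "s3")))
  res <- data.frame(snp_id = c("s1", "s2", "s3"),
                    p_trend = c(0.5, 0.02, 0.09), excluded = FALSE)
  per_gene <- best_snp_per_gene(map, res)
  units <- pool_shared_loci(map)
  per_unit <- best_snp_per_gene(map, res, units = units)
  expect_equal(nrow(per_unit), 1)
  expect_lte(per_unit$p_j, min(per_gene$p_j))
})

test_that("genes whose SNPs are all unusable are dropped and counted", {
  map <- pathgwas:::snp_gene_map(list(s1 = "gA", s2 = "gB"),
                                 list(gA = "s1", gB = "s2"))
  res <- data.frame(snp_id = c("s1", "s2"), p_trend = c(NA, 0.2),
                    excluded = c(TRUE, FALSE))
  gr <- best_snp_per_gene(map, res)
  expect_equal(gr$gene_id, "gB")
  expect_equal(attr(gr, "n_dropped_genes"), 1L)
})
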