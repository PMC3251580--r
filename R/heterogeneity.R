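#' Per-study allele-count log odds ratio
#'
#' From a 2x2 allele-count table (minor/major alleles in cases and
#' controls): `log OR = log(ad / bc)`, `se = sqrt(1/a + 1/b + 1/c + 1/d)`.
#' When any cell is zero the Haldane-Anscombe correction adds 0.5 to every
#' cell. Allele counts come from genotype dosages (each sample contributes
#' two alleles).
#'
#' @param case_minor,case_major,control_minor,control_major Allele counts.
#' @return List: `log_or`, `se`; `NULL` when a whole margin is zero (the
#'   study carries no information for this SNP).
#' @export
per_study_effect <- function(case_minor, case_major, control_minor,
                             control_major) {
  a <- case_minor; b <- case_major; c <- control_minor; d <- control_major
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    return(NULL)
  }
  if (min(a, b, c, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  list(log_or = log((a * d) / (b * c)),
       se = sqrt(1 / a + 1 / b + 1 / c + 1 / d))
}

#' Fixed-effect meta-analysis with Cochran's Q and I-squared
#'
#' Inverse-variance fixed-effect pooling of per-study log odds ratios;
#' `Q = sum w_i (theta_i - pooled)^2` with `w_i = 1/se_i^2`, `df = k - 1`,
#' `q_p` from the chi-square distribution, and
#' `I2 = max(0, 100 (Q - df) / Q)` — the percentage of variation in study
#' estimates attributable to heterogeneity rather than chance.
#'
#' @param effects data.frame with columns `log_or`, `se` (one row per
#'   study).
#' @return List: `pooled_log_or, pooled_se, Q, df, q_p, I2, k`. With a
#'   single study, `Q`/`q_p`/`I2` are `NA` (no heterogeneity test).
#' @export
cochran_q <- function(effects) {
  k <- nrow(effects)
  if (k == 0) stop("no study effects")
  w <- 1 / effects$se^2
  pooled <- sum(w * effects$log_or) / sum(w)
  pooled_se <- sqrt(1 / sum(w))
  if (k == 1) {
    return(list(pooled_log_or = pooled, pooled_se = pooled_se, Q = NA_real_,
                df = 0L, q_p = NA_real_, I2 = NA_real_, k = 1L))
  }
  Q <- sum(w * (effects$log_or - pooled)^2)
  df <- k - 1L
  q_p <- stats::pchisq(Q, df = df, lower.tail = FALSE)
  I2 <- if (Q > 0) max(0, 100 * (Q - df) / Q) else 0
  list(pooled_log_or = pooled, pooled_se = pooled_se, Q = Q, df = df,
       q_p = q_p, I2 = I2, k = k)
}

#' Per-SNP cross-study heterogeneity scan
#'
#' For every SNP, builds per-study 2x2 allele-count tables from genotype
#' dosages of cases and controls, estimates per-study per-allele ORs,
#' pools them by fixed-effect meta-analysis, and reports Cochran's Q and
#' I-squared. Studies with an empty table margin are dropped per SNP.
#'
#' @param genotypes Samples x SNPs dosage matrix.
#' @param samples Sample table (`status`, `study`).
#' @param snp_ids SNPs to analyze (default: all columns).
#' @return data.frame: `snp_id, k, pooled_or, ci_low, ci_high, q, df, q_p,
#'   i2`.
#' @export
snp_meta_scan <- function(genotypes, samples, snp_ids = colnames(genotypes)) {
  g <- genotypes[match(samples$sample_id, rownames(genotypes)), snp_ids,
                 drop = FALSE]
  studies <- split(seq_len(nrow(samples)), samples$study)
  rows <- lapply(snp_ids, function(s) {
    eff <- list()
    for (st in names(studies)) {
      ix <- studies[[st]]
      gi <- g[ix, s]
      y <- samples$status[ix]
      ok <- !is.na(gi)
      a <- sum(gi[ok & y == 1])                     # case minor alleles
      b <- 2 * sum(ok & y == 1) - a
      cc <- sum(gi[ok & y == 0])
      d <- 2 * sum(ok & y == 0) - cc
      e <- per_study_effect(a, b, cc, d)
      if (!is.null(e)) eff[[st]] <- data.frame(study = st,
                                               log_or = e$log_or,
                                               se = e$se)
    }
    if (!length(eff)) {
      return(data.frame(snp_id = s, k = 0L, pooled_or = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_, q = NA_real_,
                        df = NA_integer_, q_p = NA_real_, i2 = NA_real_))
    }
    m <- cochran_q(do.call(rbind, eff))
    data.frame(snp_id = s, k = m$k, pooled_or = exp(m$pooled_log_or),
               ci_low = exp(m$pooled_log_or - 1.96 * m$pooled_se),
               ci_high = exp(m$pooled_log_or + 1.96 * m$pooled_se),
               q = m$Q, df = m$df, q_p = m$q_p, i2 = m$I2)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flag and remove SNPs with study-heterogeneous effects
#'
#' SNPs whose Cochran's Q p-value falls below the threshold (strict `<`)
#' are removed globally from the SNP-gene map; genes left without SNPs are
#' dropped. SNPs that could not be meta-analyzed (fewer than two
#' informative studies) pass the filter by convention.
#'
#' @param meta data.frame from [snp_meta_scan()].
#' @param map A `snp_gene_map`.
#' @param threshold Q p-value removal threshold (default 0.2).
#' @return List: `removed` (character vector of SNP ids), `map` (filtered
#'   `snp_gene_map`), `dropped_genes` (genes that lost all SNPs).
#' @export
flag_and_filter <- function(meta, map, threshold = 0.2) {
  stopifnot(inherits(map, "snp_gene_map"))
  removed <- meta$snp_id[!is.na(meta$q_p) & meta$q_p < threshold]
  snp2gene <- map$snp2gene[setdiff(names(map$snp2gene), removed)]
  gene2snp <- lapply(map$gene2snp, setdiff, removed)
  empty <- names(gene2snp)[lengths(gene2snp) == 0]
  gene2snp <- gene2snp[lengths(gene2snp) > 0]
  list(removed = removed, map = snp_gene_map(snp2gene, gene2snp),
       dropped_genes = empty)
}
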