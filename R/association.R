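#' Minor-allele frequency among controls
#'
#' Complete-case allele frequency among pooled controls, folded to the
#' minor allele (always <= 0.5). SNPs rarer than 1% among controls are
#' conventionally excluded from association testing.
#'
#' @param genotypes Samples x SNPs dosage matrix.
#' @param samples Sample table (`status` 0/1) aligned to `genotypes` rows by
#'   `sample_id`.
#' @param snp_id SNP identifier (column of `genotypes`).
#' @return Frequency in \[0, 0.5\]; `NA` (with a warning) when all control
#'   genotypes are missing.
#' @export
control_maf <- function(genotypes, samples, snp_id) {
  g <- genotypes[match(samples$sample_id, rownames(genotypes)), snp_id]
  g <- g[samples$status == 0]
  g <- g[!is.na(g)]
  if (!length(g)) {
    warning("SNP ", snp_id, " has no non-missing control genotypes")
    return(NA_real_)
  }
  f <- sum(g) / (2 * length(g))
  min(f, 1 - f)
}

#' @keywords internal
control_maf_all <- function(genotypes, samples) {
  g <- genotypes[match(samples$sample_id[samples$status == 0],
                       rownames(genotypes)), , drop = FALSE]
  n_obs <- colSums(!is.na(g))
  f <- colSums(g, na.rm = TRUE) / (2 * n_obs)
  f[n_obs == 0] <- NA_real_
  pmin(f, 1 - f)
}

#' Build the covariate design matrix
#'
#' Categorical covariates (`study`, `smoking`) enter as indicator contrasts
#' (treatment coding; smoking reference "never", study reference its first
#' level); `age` numeric; `sex` and `dna_source` 0/1 indicators.
#'
#' @param samples Sample table.
#' @param covariates Character vector of covariate column names (may be
#'   empty for an intercept-only design).
#' @return Numeric design matrix including an intercept column.
#' @export
covariate_design <- function(samples,
                             covariates = c("age", "sex", "study",
                                            "dna_source", "smoking")) {
  covariates <- intersect(covariates, names(samples))
  drop_const <- function(nm) {
    # single-level factors (e.g. one study) carry no contrast
    v <- samples[[nm]]
    length(unique(v)) > 1
  }
  covariates <- Filter(drop_const, covariates)
  if (!length(covariates)) {
    return(matrix(1, nrow(samples), 1, dimnames = list(NULL, "(Intercept)")))
  }
  fml <- stats::reformulate(covariates)
  stats::model.matrix(fml, data = samples)
}

#' Covariate-adjusted 1-df logistic trend test for one SNP
#'
#' Fits `status ~ dosage + covariates` by maximum likelihood and returns
#' Wald per-allele statistics: log-OR, SE, OR with 95% CI
#' (`exp(beta +- 1.96 se)`), and the 1-df trend p-value. Missing genotypes
#' are dropped (complete-case); covariate missingness is rejected upstream.
#'
#' @param genotype_vector Named dosage vector (names = sample ids) or a
#'   plain vector aligned to `samples`.
#' @param samples Sample table.
#' @param covariates Covariate column names (default the full adjustment
#'   set).
#' @return One-row data.frame: `snp_id` (NA unless supplied), `beta, se,
#'   or_, ci_low, ci_high, p_trend, maf_controls, n_used, excluded, reason`.
#' @export
trend_test <- function(genotype_vector, samples,
                       covariates = c("age", "sex", "study", "dna_source",
                                      "smoking")) {
  if (!is.null(names(genotype_vector))) {
    genotype_vector <- genotype_vector[match(samples$sample_id,
                                             names(genotype_vector))]
  }
  ok <- !is.na(genotype_vector)
  g <- genotype_vector[ok]
  y <- samples$status[ok]
  maf <- {
    gc <- g[y == 0]
    if (length(gc)) min(sum(gc) / (2 * length(gc)),
                        1 - sum(gc) / (2 * length(gc))) else NA_real_
  }
  out <- data.frame(beta = NA_real_, se = NA_real_, or_ = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_,
                    p_trend = NA_real_, maf_controls = maf,
                    n_used = length(g), excluded = TRUE,
                    reason = NA_character_, stringsAsFactors = FALSE)
  if (length(unique(y)) < 2) {
    out$reason <- "only one outcome class"
    return(out)
  }
  if (length(unique(g)) < 2) {
    out$reason <- "constant dosage"
    return(out)
  }
  X <- covariate_design(samples[ok, , drop = FALSE], covariates)
  fit <- suppressWarnings(
    stats::glm.fit(cbind(X, dosage = g), y,
                   family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-12,
                                                maxit = 50)))
  cf <- fit$coefficients["dosage"]
  # Wald variance from the weighted cross-product at convergence
  XX <- cbind(X, dosage = g)
  W <- fit$weights
  info <- crossprod(XX * sqrt(W))
  cov_try <- try(solve(info), silent = TRUE)
  if (!fit$converged || inherits(cov_try, "try-error") ||
      !is.finite(cf) || abs(cf) > 15) {
    out$reason <- if (!fit$converged || (is.finite(cf) && abs(cf) > 15)) {
      "separation or non-convergence"
    } else "singular information matrix"
    return(out)
  }
  se <- sqrt(cov_try["dosage", "dosage"])
  z <- cf / se
  out$beta <- unname(cf)
  out$se <- unname(se)
  out$or_ <- exp(unname(cf))
  out$ci_low <- exp(unname(cf) - 1.96 * se)
  out$ci_high <- exp(unname(cf) + 1.96 * se)
  out$p_trend <- 2 * stats::pnorm(-abs(z))
  out$excluded <- FALSE
  out
}

#' Per-SNP association scan
#'
#' Applies the control-MAF filter then the covariate-adjusted trend test to
#' every SNP. SNPs failing the filter, with constant dosage, or with
#' non-convergent fits are retained in the output with `excluded = TRUE`
#' and a reason, but carry no statistics.
#'
#' @param genotypes Samples x SNPs dosage matrix.
#' @param samples Sample table.
#' @param covariates Covariate column names.
#' @param maf_min Control-MAF exclusion threshold (strict `<`).
#' @return data.frame of per-SNP results (one row per SNP).
#' @export
assoc_scan <- function(genotypes, samples,
                       covariates = c("age", "sex", "study", "dna_source",
                                      "smoking"),
                       maf_min = 0.01) {
  stopifnot(all(samples$sample_id %in% rownames(genotypes)))
  g <- genotypes[match(samples$sample_id, rownames(genotypes)), ,
                 drop = FALSE]
  mafs <- control_maf_all(g, samples)
  res <- vector("list", ncol(g))
  for (j in seq_len(ncol(g))) {
    if (is.na(mafs[j]) || mafs[j] < maf_min) {
      res[[j]] <- data.frame(beta = NA_real_, se = NA_real_, or_ = NA_real_,
                             ci_low = NA_real_, ci_high = NA_real_,
                             p_trend = NA_real_, maf_controls = mafs[j],
                             n_used = sum(!is.na(g[, j])), excluded = TRUE,
                             reason = if (is.na(mafs[j]))
                               "all controls missing" else "control MAF below threshold",
                             stringsAsFactors = FALSE)
    } else {
      res[[j]] <- trend_test(g[, j], samples, covariates)
    }
  }
  out <- do.call(rbind, res)
  out <- cbind(snp_id = colnames(g), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Best-SNP gene statistics
#'
#' Each gene (or pooled locus unit) is represented by the smallest trend
#' p-value among its retained SNPs; the gene statistic is
#' `r_j = -log10(p_j)`. Ties break to the lexicographically smaller SNP id.
#' `snp_rank` is the rank of the chosen SNP among ALL the gene's tested
#' SNPs in `snp_results` (so a rank > 1 flags that better-ranked SNPs were
#' excluded, e.g. by the heterogeneity filter).
#'
#' @param map A `snp_gene_map`.
#' @param snp_results data.frame from [assoc_scan()] (or any table with
#'   `snp_id`, `p_trend`, `excluded`).
#' @param units Optional `locus_units`; when supplied, statistics are per
#'   pooled unit (SNP set = union over members).
#' @param drop_snps Optional character vector of SNP ids to exclude (they
#'   still count for `snp_rank`).
#' @return data.frame: `gene_id, n_snps, best_snp_id, snp_rank, p_j, r_j`.
#'   Genes with no retained SNP are dropped (count reported via attribute
#'   `n_dropped_genes`).
#' @export
best_snp_per_gene <- function(map, snp_results, units = NULL,
                              drop_snps = NULL) {
  stopifnot(inherits(map, "snp_gene_map"))
  if (is.null(units)) {
    groups <- map$gene2snp
  } else {
    groups <- units$unit2snp
  }
  p_all <- stats::setNames(snp_results$p_trend, snp_results$snp_id)
  usable <- !snp_results$excluded & !is.na(snp_results$p_trend)
  if (!is.null(drop_snps)) usable <- usable & !(snp_results$snp_id %in%
                                                  drop_snps)
  p_use <- stats::setNames(ifelse(usable, snp_results$p_trend, NA_real_),
                           snp_results$snp_id)
  rows <- lapply(sort(names(groups)), function(gid) {
    snps <- sort(intersect(groups[[gid]], snp_results$snp_id))
    pu <- p_use[snps]
    if (all(is.na(pu))) return(NULL)
    best <- snps[which.min(replace(pu, is.na(pu), Inf))]  # lexicographic tie-break via sorted snps
    pa <- p_all[snps]
    rank_best <- sum(!is.na(pa) & pa < pa[best]) + 1L
    data.frame(gene_id = gid, n_snps = length(snps), best_snp_id = best,
               snp_rank = rank_best, p_j = unname(pu[best]),
               r_j = -log10(unname(pu[best])), stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), n_snps = integer(0),
                      best_snp_id = character(0), snp_rank = integer(0),
                      p_j = numeric(0), r_j = numeric(0))
  }
  rownames(out) <- NULL
  attr(out, "n_dropped_genes") <- dropped
  out
}
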