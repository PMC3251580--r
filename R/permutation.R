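#' Fit the covariate-only null model for score testing
#'
#' The genotype permutation scheme leaves outcome and covariates fixed, so
#' the logistic null model `status ~ covariates` is identical for every
#' permutation and is fit once. Its fitted probabilities and information
#' pieces feed the per-SNP 1-df score tests.
#'
#' @param samples Sample table.
#' @param covariates Covariate column names.
#' @return List with the design `X`, fitted probabilities `mu`, IRLS
#'   weights `w`, residuals `resid = y - mu`, and `XtWX_inv`.
#' @export
null_model <- function(samples,
                       covariates = c("age", "sex", "study", "dna_source",
                                      "smoking")) {
  X <- covariate_design(samples, covariates)
  y <- samples$status
  fit <- stats::glm.fit(X, y, family = stats::binomial())
  mu <- fit$fitted.values
  w <- mu * (1 - mu)
  list(X = X, y = y, mu = mu, w = w, resid = y - mu,
       XtWX_inv = solve(crossprod(X * sqrt(w))))
}

#' Vectorized per-SNP 1-df score tests
#'
#' Rao score test of the dosage term added to the null covariate model:
#' `U_j = g_j'(y - mu)`, `V_j = g_j'Wg_j - g_j'WX (X'WX)^{-1} X'Wg_j`,
#' `chi2_j = U_j^2 / V_j` on 1 df. Missing dosages are mean-imputed per SNP
#' (imputation is done once, before permuting, so every permutation sees
#' the same genotype rows). Asymptotically equivalent to the Wald trend
#' test; used for the permutation null because it needs no per-SNP model
#' fit.
#'
#' @param G Samples x SNPs dosage matrix, no NAs (see
#'   [prepare_perm_genotypes()]).
#' @param nm Null model from [null_model()].
#' @param G2 Optional precomputed `G^2` (row-permuted alongside `G` in the
#'   permutation loop to avoid re-squaring).
#' @return Vector of p-values (NA where the score variance is degenerate).
#' @export
score_test_matrix <- function(G, nm, G2 = NULL) {
  if (is.null(G2)) G2 <- G^2
  U <- drop(crossprod(G, nm$resid))
  WX <- nm$X * nm$w
  A <- crossprod(G, WX)                      # m x k
  V <- drop(crossprod(G2, nm$w)) - rowSums((A %*% nm$XtWX_inv) * A)
  p <- rep(NA_real_, length(U))
  ok <- is.finite(V) & V > 1e-12
  p[ok] <- stats::pchisq(U[ok]^2 / V[ok], df = 1, lower.tail = FALSE)
  p
}

#' Prepare a genotype matrix for the permutation engine
#'
#' Aligns rows to the sample table, restricts to retained SNPs, and
#' mean-imputes missing dosages per SNP.
#'
#' @param genotypes Samples x SNPs dosage matrix.
#' @param samples Sample table.
#' @param snp_keep Optional character vector of SNP ids to retain.
#' @return Numeric matrix without NAs.
#' @export
prepare_perm_genotypes <- function(genotypes, samples, snp_keep = NULL) {
  G <- genotypes[match(samples$sample_id, rownames(genotypes)), ,
                 drop = FALSE]
  if (!is.null(snp_keep)) G <- G[, intersect(colnames(G), snp_keep),
                                 drop = FALSE]
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  G
}

#' Gene-level p-values under genotype permutation
#'
#' The shared permutation null for both enrichment methods. Each
#' permutation reassigns whole genotype rows to individuals with ONE global
#' shuffle (outcome and covariates fixed), preserving SNP-SNP linkage
#' disequilibrium while breaking genotype-phenotype association. For the
#' observed data and every permutation, per-SNP score-test p-values are
#' computed and reduced to per-gene (or per pooled locus unit) minima. The
#' same permutations are reused by every pathway and by both GSEA and ARTP.
#'
#' @param genotypes Samples x SNPs dosage matrix.
#' @param samples Sample table (never permuted).
#' @param map A `snp_gene_map`.
#' @param covariates Covariate column names.
#' @param B Number of permutations (>= 1).
#' @param seed Integer seed; the B permutations are drawn once from it.
#' @param units Optional `locus_units` for pooled analysis.
#' @param snp_keep Optional retained SNP ids (post MAF / heterogeneity
#'   filters).
#' @return List: `obs` (named vector of observed gene p-values), `perm`
#'   (B x N matrix, columns in the order of `names(obs)`), `B`, `genes`.
#' @export
permutation_gene_p <- function(genotypes, samples, map, covariates =
                                 c("age", "sex", "study", "dna_source",
                                   "smoking"),
                               B = 1000, seed = 1, units = NULL,
                               snp_keep = NULL) {
  if (B < 1) stop("B must be >= 1")
  G <- prepare_perm_genotypes(genotypes, samples, snp_keep)
  nm <- null_model(samples, covariates)
  groups <- if (is.null(units)) map$gene2snp else units$unit2snp
  groups <- lapply(groups, intersect, colnames(G))
  groups <- groups[lengths(groups) > 0]
  groups <- groups[sort(names(groups))]
  col_idx <- lapply(groups, match, colnames(G))

  gene_min <- function(pv) {
    vapply(col_idx, function(ix) {
      v <- pv[ix]
      if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
    }, numeric(1))
  }

  G2 <- G^2
  obs <- gene_min(score_test_matrix(G, nm, G2))
  keep <- !is.na(obs)
  obs <- obs[keep]
  col_idx <- col_idx[keep]

  n <- nrow(G)
  set.seed(seed)
  perm_idx <- replicate(B, sample.int(n), simplify = FALSE)
  perm <- matrix(NA_real_, nrow = B, ncol = length(obs),
                 dimnames = list(NULL, names(obs)))
  for (b in seq_len(B)) {
    ix <- perm_idx[[b]]
    perm[b, ] <- gene_min(score_test_matrix(G[ix, , drop = FALSE], nm,
                                            G2[ix, , drop = FALSE]))
  }
  list(obs = obs, perm = perm, B = B, genes = names(obs))
}
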