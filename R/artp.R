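#' Rank-truncated products of sorted p-values
#'
#' `W(K)` is the product of the K smallest p-values in a pathway, for every
#' truncation point `K = 1..L`. Computed and returned in log space to avoid
#' underflow.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return List: `logW` (cumulative sums of sorted log p), `W`
#'   (`exp(logW)`), `K` (1..L).
#' @export
truncation_products <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  logW <- cumsum(log(sort(p_values)))
  list(logW = logW, W = exp(logW), K = seq_along(logW))
}

#' @keywords internal
#' Row-wise log W(K): each row of P sorted ascending, cumulative log-sums.
logw_rows <- function(P) {
  res <- apply(P, 1, function(p) cumsum(log(sort(p))))
  if (is.matrix(res)) t(res) else matrix(res, ncol = 1)
}

#' Adaptive rank-truncated product test for one pathway
#'
#' Two-level permutation procedure over the shared genotype-permutation
#' pool. Level 1 estimates, for the observed data and every permutation,
#' the p-value of each truncation product by its rank in the augmented
#' pool of B+1 values (observed plus permutations, ties counted as
#' exceedances, self included):
#' `s_hat_t(K) = #\{t' in pool: W_t'(K) <= W_t(K)\} / (B + 1)`,
#' so `s_hat` is never 0 and observed and permuted values are
#' exchangeable. Level 2 takes `minP = min_K s_hat(K)` and adjusts for the
#' minimization by permutation rank:
#' `p_artp = (#\{b: minP_b <= minP_obs\} + 1) / (B + 1)`.
#'
#' @param obs_gene_p Numeric vector of the pathway's observed gene
#'   p-values (length L).
#' @param perm_gene_p B x L matrix of the same genes' p-values under the
#'   shared permutations (columns aligned to `obs_gene_p`).
#' @param K_grid Truncation points to scan (default all of 1..L).
#' @return List of class `artp_result`: `L, K_grid, W, logW, sK_hat, minP,
#'   K_star, p_artp, minP_perm, B`.
#' @export
artp_pathway <- function(obs_gene_p, perm_gene_p, K_grid = NULL) {
  L <- length(obs_gene_p)
  if (L == 0) stop("pathway has no genes with data")
  perm_gene_p <- as.matrix(perm_gene_p)
  if (ncol(perm_gene_p) != L) stop("permutation matrix has wrong width")
  B <- nrow(perm_gene_p)
  if (B < 20) warning("fewer than 20 permutations: unstable ARTP estimates")
  if (is.null(K_grid)) K_grid <- seq_len(L)
  stopifnot(all(K_grid >= 1), all(K_grid <= L))

  logW_obs <- truncation_products(obs_gene_p)$logW
  logW_perm <- logw_rows(perm_gene_p)       # B x L
  nK <- length(K_grid)
  s_obs <- numeric(nK)
  s_perm <- matrix(NA_real_, B, nK)
  for (j in seq_len(nK)) {
    K <- K_grid[j]
    v <- logW_perm[, K]
    o <- logW_obs[K]
    s_obs[j] <- (sum(v <= o) + 1) / (B + 1)
    # each permutation ranked in the augmented pool (self + observed)
    s_perm[, j] <- (rank(v, ties.method = "max") + (o <= v)) / (B + 1)
  }
  minP_obs <- min(s_obs)
  minP_perm <- apply(s_perm, 1, min)
  p_artp <- (sum(minP_perm <= minP_obs) + 1) / (B + 1)
  structure(list(L = L, K_grid = K_grid, W = exp(logW_obs),
                 logW = logW_obs, sK_hat = s_obs, minP = minP_obs,
                 K_star = K_grid[which.min(s_obs)], p_artp = p_artp,
                 minP_perm = minP_perm, B = B),
            class = "artp_result")
}

#' @export
print.artp_result <- function(x, ...) {
  cat("ARTP: L =", x$L, " K* =", x$K_star,
      " minP =", signif(x$minP, 3),
      " p_artp =", signif(x$p_artp, 4), "\n")
  invisible(x)
}

#' ARTP over all pathways against the shared permutation null
#'
#' Applies [artp_pathway()] to every pathway using pathway-restricted
#' columns of the shared gene-p matrix; identical permutation indices
#' across pathways keep results comparable.
#'
#' @param db A `pathway_db`.
#' @param engine Result of [permutation_gene_p()].
#' @param K_max Optional cap on the truncation grid (default: all 1..L).
#' @return List: `table` (data.frame `set_id, n_genes, n_genes_with_data,
#'   k_star, minp, p_artp`), `minp_perm` (pathways x B matrix of
#'   permutation minP, for normalization/FDR).
#' @export
artp_all <- function(db, engine, K_max = Inf) {
  stopifnot(inherits(db, "pathway_db"))
  genes <- engine$genes
  rows <- list()
  mp <- list()
  for (id in names(db$sets)) {
    members <- intersect(db$sets[[id]], genes)
    if (length(members) < 1) {
      message("pathway ", id, " skipped: no genes with data")
      next
    }
    ix <- match(members, genes)
    K_grid <- seq_len(min(length(members), K_max))
    res <- artp_pathway(engine$obs[ix], engine$perm[, ix, drop = FALSE],
                        K_grid = K_grid)
    rows[[id]] <- data.frame(set_id = id, n_genes = length(db$sets[[id]]),
                             n_genes_with_data = length(members),
                             k_star = res$K_star, minp = res$minP,
                             p_artp = res$p_artp, stringsAsFactors = FALSE)
    mp[[id]] <- res$minP_perm
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  pm <- if (length(mp)) do.call(rbind, mp) else
    matrix(numeric(0), 0, engine$B)
  list(table = tab, minp_perm = pm, B = engine$B)
}
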