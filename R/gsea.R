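#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Genes are ranked by their statistic `r_j = -log10(p_j)` in decreasing
#' order. Walking down the ranking, the running sum gains
#' `r_j^weight_p / N_R` at pathway members (`N_R` = sum of member
#' `r^weight_p`) and loses `1 / (N - N_H)` at non-members; the enrichment
#' score is the maximum of the running sum (enrichment direction only).
#' Ties in `r_j` are broken by gene id for reproducibility.
#'
#' @param gene_stats Named numeric vector of gene statistics `r_j`
#'   (any order; sorted internally, decreasing).
#' @param membership Character vector of member gene ids.
#' @param weight_p Exponent on `r_j` in the hit increment (default 1;
#'   0 gives the classical unweighted KS statistic).
#' @return The enrichment score (scalar). `NA` with a warning when
#'   `N_H = 0` or `N_H = N`; when all member statistics are 0
#'   (`N_R = 0`), the defined limit `-N_H / (N - N_H)` with a warning.
#' @export
enrichment_score <- function(gene_stats, membership, weight_p = 1) {
  ord <- order(-gene_stats, names(gene_stats))
  r <- gene_stats[ord]
  hit <- names(r) %in% membership
  N <- length(r)
  N_H <- sum(hit)
  if (N_H == 0 || N_H == N) {
    warning("enrichment score undefined: pathway covers none or all genes")
    return(NA_real_)
  }
  rw <- abs(r)^weight_p
  N_R <- sum(rw[hit])
  if (N_R == 0) {
    warning("all member statistics are zero; ES at its defined limit")
    return(-N_H / (N - N_H))
  }
  steps <- ifelse(hit, rw / N_R, -1 / (N - N_H))
  max(cumsum(steps))
}

#' @keywords internal
#' Fast ES from precomputed ranking: positions of hits in the decreasing
#' ranking and their weights. The running sum peaks only at hit positions.
es_at_positions <- function(pos, w_hit, N, N_H) {
  N_R <- sum(w_hit)
  if (N_R == 0) return(-N_H / (N - N_H))
  o <- order(pos)
  pos <- pos[o]
  cum_hit <- cumsum(w_hit[o]) / N_R
  miss <- (pos - seq_len(N_H)) / (N - N_H)
  max(cum_hit - miss)
}

#' Empirical permutation p-value for an enrichment score
#'
#' `p = #\{b: ES_b >= ES_obs\} / B`; ties count as exceedances
#' (conservative). A zero count is reported as 0 numerically; use
#' [format_perm_p()] for the conventional "<1/B" display.
#'
#' @param obs_es Observed enrichment score.
#' @param perm_es Numeric vector of permutation enrichment scores.
#' @return Empirical p-value in \[0, 1\].
#' @export
gsea_pvalue <- function(obs_es, perm_es) {
  if (!length(perm_es)) stop("empty permutation vector")
  mean(perm_es >= obs_es)
}

#' Display convention for permutation p-values
#' @param p Numeric p-value(s).
#' @param B Permutation count.
#' @return Character; zero counts render as `"<1/B"`.
#' @export
format_perm_p <- function(p, B) {
  ifelse(p <= 0, paste0("<", format(1 / B, digits = 2)),
         format(p, digits = 3))
}

#' GSEA over all pathways against the shared permutation null
#'
#' Computes the observed enrichment score per pathway from the observed
#' gene p-values and its empirical p-value against enrichment scores
#' recomputed on every permutation of the shared gene-p matrix.
#'
#' @param db A `pathway_db` (gene ids must match the engine's gene names;
#'   for pooled analyses, unit ids).
#' @param engine Result of [permutation_gene_p()].
#' @param weight_p Exponent on `r_j` (default 1).
#' @return List: `table` (data.frame `set_id, n_genes, n_genes_with_data,
#'   es, p_gsea`), `perm_es` (pathways x B matrix of permutation scores,
#'   for normalization/FDR).
#' @export
gsea_scan <- function(db, engine, weight_p = 1) {
  stopifnot(inherits(db, "pathway_db"))
  genes <- engine$genes
  N <- length(genes)
  r_obs <- -log10(engine$obs)
  R_perm <- -log10(engine$perm)            # B x N
  B <- engine$B

  # rank positions computed once per permutation, shared by all pathways
  pos_of <- function(r) {
    ord <- order(-r, genes)
    p <- integer(N)
    p[ord] <- seq_len(N)
    p
  }
  pos_obs <- pos_of(r_obs)
  pos_perm <- vapply(seq_len(B), function(b) pos_of(R_perm[b, ]),
                     integer(N))                  # N x B

  ids <- names(db$sets)
  rows <- list()
  perm_es <- list()
  for (id in ids) {
    members <- intersect(db$sets[[id]], genes)
    N_H <- length(members)
    if (N_H == 0 || N_H == N) {
      warning("pathway ", id, " skipped (no usable gene split)")
      next
    }
    m_idx <- match(members, genes)
    es_o <- es_at_positions(pos_obs[m_idx], abs(r_obs[m_idx])^weight_p,
                            N, N_H)
    es_b <- vapply(seq_len(B), function(b) {
      es_at_positions(pos_perm[m_idx, b],
                      abs(R_perm[b, m_idx])^weight_p, N, N_H)
    }, numeric(1))
    rows[[id]] <- data.frame(set_id = id, n_genes = length(db$sets[[id]]),
                             n_genes_with_data = N_H, es = es_o,
                             p_gsea = gsea_pvalue(es_o, es_b),
                             stringsAsFactors = FALSE)
    perm_es[[id]] <- es_b
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  pm <- if (length(perm_es)) do.call(rbind, perm_es) else
    matrix(numeric(0), 0, B)
  list(table = tab, perm_es = pm, B = B)
}

#' @keywords internal
es_for_stats <- function(r, m_idx, N, N_H, weight_p) {
  ord <- order(-r, names(r) %||% seq_along(r))
  pos_of <- integer(N)
  pos_of[ord] <- seq_len(N)
  pos <- pos_of[m_idx]
  w <- abs(r[m_idx])^weight_p
  es_at_positions(pos, w, N, N_H)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
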