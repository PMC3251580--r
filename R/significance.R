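#' Normalize a pathway statistic against its permutation distribution
#'
#' `NS = (obs - mean(perm)) / sd(perm)`, applied both to the observed
#' statistic and to every permutation value. Each pathway is normalized by
#' its own permutation mean and SD, which makes pathways of different sizes
#' and gene compositions directly comparable.
#'
#' @param obs Observed statistic (scalar).
#' @param perm Numeric vector of the statistic over permutations
#'   (length >= 2, SD > 0).
#' @return List: `ns` (observed normalized score), `ns_perm` (normalized
#'   permutation values).
#' @export
normalize_score <- function(obs, perm) {
  perm <- perm[is.finite(perm)]
  if (length(perm) < 2) stop("need >= 2 finite permutation values")
  s <- stats::sd(perm)
  if (!is.finite(s) || s <= 0) stop("permutation SD is zero")
  m <- mean(perm)
  list(ns = (obs - m) / s, ns_perm = (perm - m) / s)
}

#' Normalized scores for a whole scan
#'
#' GSEA statistics normalize on the enrichment-score scale; ARTP statistics
#' are mapped to `-log(minP)` first so that for both methods a larger
#' normalized score means more significant. Pathways with zero permutation
#' SD are flagged and excluded from the FDR.
#'
#' @param obs Named numeric vector of observed statistics (one per
#'   pathway).
#' @param perm Pathways x B matrix of permutation statistics (rows aligned
#'   with `obs`).
#' @param neg_log Apply `-log` to both observed and permutation values
#'   first (use for minP-type statistics).
#' @return List: `ns` (named vector), `ns_perm` (matrix), `excluded`
#'   (character vector of flagged pathways).
#' @export
normalize_scan <- function(obs, perm, neg_log = FALSE) {
  stopifnot(length(obs) == nrow(perm))
  if (neg_log) {
    obs <- -log(obs)
    perm <- -log(perm)
  }
  ids <- names(obs)
  ns <- stats::setNames(rep(NA_real_, length(obs)), ids)
  ns_perm <- matrix(NA_real_, nrow(perm), ncol(perm),
                    dimnames = list(ids, NULL))
  excluded <- character(0)
  for (i in seq_along(obs)) {
    z <- try(normalize_score(obs[i], perm[i, ]), silent = TRUE)
    if (inherits(z, "try-error")) {
      excluded <- c(excluded, ids[i])
    } else {
      ns[i] <- z$ns
      ns_perm[i, ] <- z$ns_perm
    }
  }
  if (length(excluded)) {
    warning(length(excluded), " pathway(s) excluded from FDR ",
            "(degenerate permutation distribution)")
  }
  keep <- !ids %in% excluded
  list(ns = ns[keep], ns_perm = ns_perm[keep, , drop = FALSE],
       excluded = excluded)
}

#' Permutation-based false discovery rate
#'
#' At each observed normalized score `s*`, the FDR is the ratio of the
#' expected fraction of permutation scores reaching `s*` to the observed
#' fraction reaching it:
#' `FDR(s*) = [#\{perm NS >= s*\} / (B M)] / [#\{obs NS >= s*\} / M]`,
#' clipped to \[0, 1\] and made monotone non-increasing in `s*` by a
#' cumulative minimum from the largest score downward.
#'
#' @param ns Named vector of observed normalized scores (M pathways).
#' @param ns_perm M x B matrix of normalized permutation scores.
#' @return Named vector of FDR values aligned with `ns`.
#' @export
fdr_table <- function(ns, ns_perm) {
  stopifnot(length(ns) == nrow(ns_perm))
  M <- length(ns)
  allperm <- as.vector(ns_perm)
  BM <- length(allperm)
  raw <- vapply(ns, function(s) {
    num <- sum(allperm >= s) / BM
    den <- sum(ns >= s) / M
    num / den
  }, numeric(1))
  raw <- pmin(pmax(raw, 0), 1)
  # walk from least to most significant so FDR is non-increasing in NS
  ord <- order(ns)
  raw[ord] <- cummin(raw[ord])
  raw
}
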