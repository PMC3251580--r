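# Independent oracles used across tests. Each re-derives its quantity from
# first principles (explicit loops, no log-space tricks, no shared code with
# the implementation).

# Newton-Raphson logistic fit on a collapsed 2x3 genotype table.
# n0, n1: counts of controls / cases at dosage 0, 1, 2. Returns c(alpha, beta).
oracle_newton_trend <- function(n0, n1) {
  d <- c(0, 1, 2, 0, 1, 2)
  y <- c(1, 1, 1, 0, 0, 0)
  w <- c(n1, n0)
  X <- cbind(1, d)
  beta <- c(0, 0)
  for (it in 1:100) {
    p <- stats::plogis(X %*% beta)
    g <- crossprod(X, w * (y - p))
    H <- crossprod(X, X * as.vector(w * p * (1 - p)))
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-13) break
  }
  as.vector(beta)
}

# Brute-force weighted-KS enrichment score: literal running sum over the
# decreasing ranking (ties broken by gene id).
oracle_es <- function(r, members, weight_p = 1) {
  ord <- order(-r, names(r))
  r <- r[ord]
  run <- 0
  best <- -Inf
  N <- length(r)
  NH <- sum(names(r) %in% members)
  NR <- sum(abs(r[names(r) %in% members])^weight_p)
  for (j in seq_len(N)) {
    if (names(r)[j] %in% members) {
      run <- run + abs(r[j])^weight_p / NR
    } else {
      run <- run - 1 / (N - NH)
    }
    best <- max(best, run)
  }
  best
}

# Exhaustive two-level ARTP enumeration: plain products, explicit counting.
oracle_artp <- function(obs_p, perm_p) {
  L <- length(obs_p)
  B <- nrow(perm_p)
  W <- function(p) {
    sp <- sort(p)
    sapply(seq_len(L), function(K) prod(sp[1:K]))
  }
  W_obs <- W(obs_p)
  W_perm <- t(apply(perm_p, 1, W))
  if (L == 1) W_perm <- matrix(W_perm, ncol = 1)
  # rank every member of the augmented pool {observed, permutations}
  s_obs <- sapply(seq_len(L), function(K) {
    pool <- c(W_obs[K], W_perm[, K])
    sum(pool <= W_obs[K]) / (B + 1)
  })
  s_perm <- matrix(NA_real_, B, L)
  for (b in seq_len(B)) {
    for (K in seq_len(L)) {
      pool <- c(W_obs[K], W_perm[, K])
      s_perm[b, K] <- sum(pool <= W_perm[b, K]) / (B + 1)
    }
  }
  minP_obs <- min(s_obs)
  minP_perm <- apply(s_perm, 1, min)
  (sum(minP_perm <= minP_obs) + 1) / (B + 1)
}

# Synthetic SNP-gene map reproducing the shared-locus structure of the
# 11-gene aromatic-amine metabolism pathway (three clusters of genes with
# overlapping SNPs: the CYP1A, UGT1A and SULT1A loci). Synthetic: built for
# the pooling worked example, not read from any genotype data.
aa_cluster_map_synthetic <- function() {
  snp2gene <- list(
    rs2472297  = c("CYP1A1", "CYP1A2"),
    rs4148328  = c("UGT1A4", "UGT1A6"),
    rs11892031 = c("UGT1A9", "UGT1A6"),
    rs1968752  = c("SULT1A1", "SULT1A2"),
    rs4646249  = "NAT2",
    rs9650592  = "NAT1",
    rs1437135  = "NQO1",
    rs2855658  = "CYP1B1"
  )
  gene2snp <- list()
  for (s in names(snp2gene)) {
    for (g in snp2gene[[s]]) gene2snp[[g]] <- sort(c(gene2snp[[g]], s))
  }
  pathgwas:::snp_gene_map(snp2gene, gene2snp)
}

# Small sample-table builder for direct trend-test inputs.
make_samples <- function(status, age = 50, sex = 0, study = "s1",
                         dna_source = 0, smoking = "never") {
  n <- length(status)
  data.frame(sample_id = sprintf("i%04d", seq_len(n)), status = status,
             age = rep_len(age, n), sex = rep_len(sex, n),
             study = rep_len(study, n),
             dna_source = rep_len(dna_source, n),
             smoking = rep_len(smoking, n), stringsAsFactors = FALSE)
}
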