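#' Simulation configuration for synthetic multi-study case-control GWAS
#'
#' Defaults emulate the study conditions of a five-study bladder-cancer
#' GWAS of European background: 3,532 cases and 5,120 controls across five
#' studies, SNPs in LD blocks laid out so the 20 kb/10 kb flanking rule
#' maps each gene to its intended SNPs, MAF uniform on 0.01-0.5, pathways
#' of 5-100 genes, and per-allele ORs for causal SNPs in the 0.77-1.27
#' range. Covariates mimic a case-control study of a smoking-related
#' cancer: age uniform on 40-75, sex and DNA source Bernoulli(0.5),
#' smoking in four categories with a strong current-smoking effect.
#'
#' @param n_studies Number of studies.
#' @param n_cases,n_controls Retained counts per study (scalars recycled or
#'   vectors of length `n_studies`).
#' @param n_snps Number of SNPs.
#' @param block_size SNPs per LD block.
#' @param within_block_rho AR(1) latent correlation within a block, in
#'   \[0, 1).
#' @param maf_range Minor-allele-frequency interval (within
#'   \[0.005, 0.5\]).
#' @param genes_per_block Genes laid out per LD block.
#' @param n_pathways Number of gene sets to generate.
#' @param pathway_size_range Inclusive gene-count interval for generated
#'   sets (default 5-100).
#' @param causal List of causal configurations, each a list with
#'   `pathway` (index into the generated sets), `n_causal_genes`, and
#'   `log_or` (scalar, or per-study vector of length `n_studies`; a
#'   non-constant vector injects cross-study heterogeneity).
#' @param covariate_spec List: `age_range`, `sex_p`, `dna_source_p`,
#'   `smoking_probs` (named never/former/occasional/current).
#' @param covariate_effects List of log-ORs: `age` (per year, centred),
#'   `sex`, `dna_source`, `smoking` (named former/occasional/current;
#'   never = reference).
#' @param study_intercepts Baseline logits per study.
#' @param cohort_multiplier Simulated cohort size per study =
#'   `cohort_multiplier * (n_cases + n_controls)`; cases and controls are
#'   subsampled retrospectively from the cohort.
#' @param seed Integer seed recorded in output metadata; all generator
#'   randomness derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_studies = 5,
                       n_cases = c(707, 707, 706, 706, 706),
                       n_controls = rep(1024, 5),
                       n_snps = 2000,
                       block_size = 4,
                       within_block_rho = 0.8,
                       maf_range = c(0.01, 0.5),
                       genes_per_block = 1,
                       n_pathways = 100,
                       pathway_size_range = c(5, 100),
                       causal = list(),
                       covariate_spec = list(
                         age_range = c(40, 75), sex_p = 0.5,
                         dna_source_p = 0.5,
                         smoking_probs = c(never = 0.25, former = 0.30,
                                           occasional = 0.10,
                                           current = 0.35)),
                       covariate_effects = list(
                         age = 0.02, sex = 0.4, dna_source = 0,
                         smoking = c(former = 0.5, occasional = 0.3,
                                     current = 1.1)),
                       study_intercepts = rep(-1, n_studies),
                       cohort_multiplier = 4,
                       seed = 1) {
  n_cases <- rep_len(n_cases, n_studies)
  n_controls <- rep_len(n_controls, n_studies)
  study_intercepts <- rep_len(study_intercepts, n_studies)
  stopifnot(all(n_cases > 0), all(n_controls > 0), n_snps > 0,
            block_size > 0, genes_per_block > 0, n_pathways >= 0,
            within_block_rho >= 0, within_block_rho < 1,
            cohort_multiplier >= 1)
  if (block_size > n_snps) stop("block_size exceeds n_snps")
  if (maf_range[1] < 0.005 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must lie within [0.005, 0.5]")
  }
  if (pathway_size_range[1] < 1 ||
      pathway_size_range[1] > pathway_size_range[2]) {
    stop("invalid pathway_size_range")
  }
  for (cs in causal) {
    lo <- cs$log_or
    if (!(length(lo) %in% c(1L, n_studies))) {
      stop("causal log_or must be scalar or length n_studies")
    }
  }
  structure(list(n_studies = n_studies, n_cases = n_cases,
                 n_controls = n_controls, n_snps = n_snps,
                 block_size = block_size,
                 within_block_rho = within_block_rho,
                 maf_range = maf_range, genes_per_block = genes_per_block,
                 n_pathways = n_pathways,
                 pathway_size_range = pathway_size_range, causal = causal,
                 covariate_spec = covariate_spec,
                 covariate_effects = covariate_effects,
                 study_intercepts = study_intercepts,
                 cohort_multiplier = cohort_multiplier, seed = seed),
            class = "sim_config")
}

#' @keywords internal
cohort_sizes <- function(config) {
  ceiling(config$cohort_multiplier * (config$n_cases + config$n_controls))
}

#' Simulate cohort genotypes in LD blocks with gene annotation
#'
#' One latent-Gaussian draw per haplotype per LD block with AR(1)
#' correlation `within_block_rho`, thresholded at each SNP's drawn MAF;
#' the two allele indicators sum to the 0/1/2 dosage (Hardy-Weinberg
#' within blocks, decaying pairwise LD). SNPs sit 1 kb apart within a
#' gene; genes in a block are 40 kb apart and blocks 1 Mb apart, so the
#' 20 kb upstream / 10 kb downstream rule recovers exactly the intended
#' SNP-to-gene layout without cross-gene bleed.
#'
#' @param config A `sim_config`.
#' @param n_total Number of individuals to draw (default: the full cohort
#'   implied by the config).
#' @return List: `genotypes` (n x n_snps dosage matrix), `snps` (SNP
#'   table), `genes` (gene models, 1-based inclusive), `maf` (drawn MAFs),
#'   `gene_of_snp` (named character: intended gene per SNP).
#' @export
simulate_genotypes <- function(config, n_total = sum(cohort_sizes(config))) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$n_snps
  bs <- config$block_size
  rho <- config$within_block_rho
  n_blocks <- ceiling(m / bs)
  block_of <- rep(seq_len(n_blocks), each = bs)[seq_len(m)]
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  thr <- stats::qnorm(maf)

  draw_block <- function(cols) {
    c_len <- length(cols)
    hap <- function() {
      e <- matrix(stats::rnorm(n_total * c_len), n_total, c_len)
      z <- e
      if (c_len > 1 && rho > 0) {
        for (j in 2:c_len) z[, j] <- rho * z[, j - 1] +
            sqrt(1 - rho^2) * e[, j]
      }
      z
    }
    a1 <- sweep(hap(), 2, thr[cols], `<`)
    a2 <- sweep(hap(), 2, thr[cols], `<`)
    a1 + a2
  }
  G <- matrix(0, n_total, m)
  for (blk in seq_len(n_blocks)) {
    cols <- which(block_of == blk)
    G[, cols] <- draw_block(cols)
  }
  snp_ids <- sprintf("snp%05d", seq_len(m))
  colnames(G) <- snp_ids
  rownames(G) <- sprintf("ind%06d", seq_len(n_total))

  # layout: genes_per_block consecutive SNP groups per block
  gpb <- config$genes_per_block
  gene_index <- integer(m)
  pos <- integer(m)
  gene_rows <- list()
  gid <- 0L
  for (blk in seq_len(n_blocks)) {
    cols <- which(block_of == blk)
    base <- (blk - 1L) * 1000000L + 100000L
    grp <- rep(seq_len(gpb), length.out = length(cols)) |> sort()
    offset <- 0L
    for (g in unique(grp)) {
      gc <- cols[grp == g]
      gid <- gid + 1L
      p <- base + offset + (seq_along(gc) - 1L) * 1000L
      pos[gc] <- p
      gene_index[gc] <- gid
      gene_rows[[gid]] <- data.frame(
        gene_id = sprintf("gene%04d", gid), chrom = "chr1",
        start = p[1], end = p[length(p)],
        strand = if (gid %% 2 == 1) "+" else "-",
        stringsAsFactors = FALSE)
      offset <- offset + (length(gc) - 1L) * 1000L + 40000L
    }
  }
  genes <- do.call(rbind, gene_rows)
  snps <- data.frame(snp_id = snp_ids, chrom = "chr1", pos = pos,
                     allele_a = "A", allele_b = "B",
                     stringsAsFactors = FALSE)
  list(genotypes = G, snps = snps, genes = genes, maf = maf,
       gene_of_snp = stats::setNames(sprintf("gene%04d", gene_index),
                                     snp_ids))
}

#' Generate gene sets and the causal ground-truth skeleton
#'
#' Random sets of sizes drawn from `pathway_size_range` (capped at the
#' number of genes minus one so no set covers all genes). Causal
#' configurations pin their causal genes into the designated set and pick
#' one causal SNP per causal gene (the gene's middle SNP).
#'
#' @param config A `sim_config`.
#' @param geno A result of [simulate_genotypes()].
#' @return List: `db` (a `pathway_db`), `causal_snps` (data.frame
#'   `snp_id, gene_id, pathway` plus a `log_or` matrix attribute),
#'   `enriched_pathways`, `heterogeneous_snps`.
#' @export
simulate_pathways <- function(config, geno) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  gene_ids <- geno$genes$gene_id
  n_genes <- length(gene_ids)
  lo <- config$pathway_size_range[1]
  hi <- min(config$pathway_size_range[2], n_genes - 1L)
  if (hi < lo) stop("too few genes for the requested pathway sizes")
  np <- config$n_pathways
  sizes <- if (np) sample(lo:hi, np, replace = TRUE) else integer(0)
  ids <- sprintf("pw%04d", seq_len(np))
  sets <- lapply(sizes, function(s) sort(sample(gene_ids, s)))
  names(sets) <- ids

  snps_of_gene <- split(names(geno$gene_of_snp), geno$gene_of_snp)
  causal_rows <- list()
  log_or_rows <- list()
  for (ci in seq_along(config$causal)) {
    cs <- config$causal[[ci]]
    pw <- if (is.character(cs$pathway)) cs$pathway else ids[cs$pathway]
    if (!pw %in% ids) stop("causal entry references unknown pathway")
    members <- sets[[pw]]
    if (cs$n_causal_genes > length(members)) {
      # grow the set to hold the causal genes
      extra <- sample(setdiff(gene_ids, members),
                      cs$n_causal_genes - length(members))
      members <- sort(c(members, extra))
      sets[[pw]] <- members
    }
    cg <- sample(members, cs$n_causal_genes)
    lor <- rep_len(cs$log_or, config$n_studies)
    for (g in cg) {
      gs <- snps_of_gene[[g]]
      snp <- gs[ceiling(length(gs) / 2)]
      causal_rows[[length(causal_rows) + 1L]] <-
        data.frame(snp_id = snp, gene_id = g, pathway = pw,
                   stringsAsFactors = FALSE)
      log_or_rows[[length(log_or_rows) + 1L]] <- lor
    }
  }
  causal_snps <- if (length(causal_rows)) do.call(rbind, causal_rows) else
    data.frame(snp_id = character(0), gene_id = character(0),
               pathway = character(0))
  log_or <- if (length(log_or_rows)) do.call(rbind, log_or_rows) else
    matrix(0, 0, config$n_studies)
  rownames(log_or) <- causal_snps$snp_id
  het <- causal_snps$snp_id[apply(log_or, 1,
                                  function(v) length(unique(v)) > 1)]
  nonzero <- apply(log_or, 1, function(v) any(v != 0))
  db <- pathway_db(sets, stats::setNames(rep("Self", np), ids))
  list(db = db, causal_snps = causal_snps, log_or = log_or,
       enriched_pathways = unique(causal_snps$pathway[nonzero]),
       heterogeneous_snps = het)
}

#' Simulate disease status and retrospectively sample cases and controls
#'
#' Each cohort member gets covariates and a disease status drawn from a
#' logistic model with a study-specific intercept, covariate effects, and
#' the per-study causal-SNP log-ORs; the configured numbers of cases and
#' controls per study are then subsampled (retrospective case-control
#' design, which keeps the logistic trend test well-specified).
#'
#' @param geno Result of [simulate_genotypes()] on the full cohort.
#' @param pw Result of [simulate_pathways()].
#' @param config A `sim_config`.
#' @return List: `samples` (retained sample table), `truth` (ground-truth
#'   list: causal SNPs with per-study log-ORs, enriched pathway ids,
#'   heterogeneous SNP ids, seed).
#' @export
simulate_phenotypes <- function(geno, pw, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  sizes <- cohort_sizes(config)
  n_total <- sum(sizes)
  if (nrow(geno$genotypes) < n_total) {
    stop("genotype cohort smaller than required by the config")
  }
  study <- rep(sprintf("study%d", seq_len(config$n_studies)), sizes)
  cv <- config$covariate_spec
  age <- sample(seq(cv$age_range[1], cv$age_range[2]), n_total,
                replace = TRUE)
  sex <- stats::rbinom(n_total, 1, cv$sex_p)
  dna <- stats::rbinom(n_total, 1, cv$dna_source_p)
  smoking <- sample(names(cv$smoking_probs), n_total, replace = TRUE,
                    prob = cv$smoking_probs)
  ce <- config$covariate_effects
  eta <- config$study_intercepts[match(study,
                                       sprintf("study%d",
                                               seq_len(config$n_studies)))] +
    ce$age * (age - mean(cv$age_range)) + ce$sex * sex +
    ce$dna_source * dna +
    ifelse(smoking == "never", 0, ce$smoking[smoking])
  if (nrow(pw$causal_snps)) {
    sidx <- match(study, sprintf("study%d", seq_len(config$n_studies)))
    for (r in seq_len(nrow(pw$causal_snps))) {
      g <- geno$genotypes[seq_len(n_total), pw$causal_snps$snp_id[r]]
      eta <- eta + g * pw$log_or[r, sidx]
    }
  }
  status <- stats::rbinom(n_total, 1, stats::plogis(eta))

  keep <- integer(0)
  for (s in seq_len(config$n_studies)) {
    ix <- which(study == sprintf("study%d", s))
    cases <- ix[status[ix] == 1]
    ctrls <- ix[status[ix] == 0]
    if (length(cases) < config$n_cases[s] ||
        length(ctrls) < config$n_controls[s]) {
      stop("cohort too small to meet the case/control quota for study", s,
           "; increase cohort_multiplier")
    }
    keep <- c(keep, sample(cases, config$n_cases[s]),
              sample(ctrls, config$n_controls[s]))
  }
  keep <- sort(keep)
  samples <- data.frame(
    sample_id = rownames(geno$genotypes)[keep], status = status[keep],
    age = age[keep], sex = sex[keep], study = study[keep],
    dna_source = dna[keep], smoking = smoking[keep],
    stringsAsFactors = FALSE)
  truth <- list(causal_snps = pw$causal_snps, log_or = pw$log_or,
                enriched_pathways = pw$enriched_pathways,
                heterogeneous_snps = pw$heterogeneous_snps,
                seed = config$seed)
  list(samples = validate_samples(samples), truth = truth)
}

#' Simulate a complete synthetic GWAS dataset
#'
#' Runs genotype, pathway, and phenotype generation in sequence and
#' restricts the genotype matrix to the retained case-control sample.
#'
#' @param config A `sim_config`.
#' @return List: `genotypes, samples, snps, genes, db, truth, config`.
#' @export
simulate_dataset <- function(config) {
  geno <- simulate_genotypes(config)
  pw <- simulate_pathways(config, geno)
  ph <- simulate_phenotypes(geno, pw, config)
  g <- geno$genotypes[ph$samples$sample_id, , drop = FALSE]
  list(genotypes = g, samples = ph$samples, snps = geno$snps,
       genes = geno$genes, db = pw$db, truth = ph$truth, config = config)
}

#' Write a simulated dataset to disk
#'
#' Emits the pipeline's input formats: genotype TSV, sample TSV, SNP table
#' TSV, gene BED, pathway GMT, a ground-truth JSON sidecar, and a manifest
#' recording the seed. Fails with a validation error listing offending ids
#' if the tables disagree.
#'
#' @param dataset Result of [simulate_dataset()].
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_dataset <- function(dataset, outdir) {
  bad_snp <- setdiff(colnames(dataset$genotypes), dataset$snps$snp_id)
  bad_sam <- setdiff(rownames(dataset$genotypes),
                     dataset$samples$sample_id)
  bad_gene <- setdiff(unique(unlist(dataset$db$sets)),
                      dataset$genes$gene_id)
  if (length(c(bad_snp, bad_sam, bad_gene))) {
    stop("id mismatch across tables: ",
         paste(utils::head(c(bad_snp, bad_sam, bad_gene), 10),
               collapse = ", "))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(dataset$genotypes, file.path(outdir, "genotypes.tsv"))
  write_samples(dataset$samples, file.path(outdir, "samples.tsv"))
  write_snp_table(dataset$snps, file.path(outdir, "snps.tsv"))
  write_gene_bed(dataset$genes, file.path(outdir, "genes.bed"))
  write_gmt(dataset$db, file.path(outdir, "pathways.gmt"))
  truth <- dataset$truth
  truth$log_or <- as.data.frame(truth$log_or)
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(seed = dataset$config$seed,
                            n_snps = dataset$config$n_snps,
                            n_studies = dataset$config$n_studies),
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(outdir)
}

#' Read a dataset directory written by [write_dataset()]
#' @param dir Dataset directory.
#' @return List with `genotypes, samples, snps, genes, db, truth`.
#' @export
read_dataset <- function(dir) {
  list(genotypes = read_genotypes(file.path(dir, "genotypes.tsv")),
       samples = read_samples(file.path(dir, "samples.tsv")),
       snps = read_snp_table(file.path(dir, "snps.tsv")),
       genes = read_gene_bed(file.path(dir, "genes.bed")),
       db = load_gene_sets(file.path(dir, "pathways.gmt")),
       truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                   simplifyVector = TRUE))
}
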