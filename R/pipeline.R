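#' Run the full pathway analysis
#'
#' End-to-end chain: SNP-to-gene mapping (20 kb/10 kb rule), pathway size
#' filtering, per-SNP covariate-adjusted trend tests with the control-MAF
#' filter, per-SNP cross-study heterogeneity meta-analysis with removal of
#' study-inconsistent SNPs, the shared genotype-permutation engine run on
#' the pre-filter and post-filter SNP sets, GSEA and ARTP per pathway on
#' both states, and permutation-normalized scores with a permutation FDR.
#' The report carries post-filter values with the pre-filter values in
#' companion columns.
#'
#' @param genotypes Samples x SNPs dosage matrix.
#' @param samples Sample table.
#' @param snps SNP coordinate table.
#' @param genes Gene models (1-based inclusive).
#' @param db A `pathway_db`.
#' @param covariates Covariate column names.
#' @param upstream,downstream Gene flank sizes (bp).
#' @param min_genes,max_genes Pathway size bounds.
#' @param maf_min Control-MAF exclusion threshold.
#' @param het_threshold Heterogeneity Q p-value removal threshold.
#' @param B Permutation count shared by GSEA and ARTP.
#' @param seed Seed for the permutation engine.
#' @param weight_p GSEA weight exponent.
#' @param pool_loci Pool genes sharing mapped SNPs into locus units.
#' @param run_heterogeneity Set `FALSE` to skip the heterogeneity stage
#'   (single-study designs skip it automatically).
#' @return List of class `pathway_run`: `report` (joint data.frame),
#'   `snp_results`, `gene_results`, `meta`, `removed_snps`, `manifest`.
#' @export
run_pathway_analysis <- function(genotypes, samples, snps, genes, db,
                                 covariates = c("age", "sex", "study",
                                                "dna_source", "smoking"),
                                 upstream = 20000, downstream = 10000,
                                 min_genes = 5, max_genes = 100,
                                 maf_min = 0.01, het_threshold = 0.2,
                                 B = 1000, seed = 1, weight_p = 1,
                                 pool_loci = FALSE,
                                 run_heterogeneity = TRUE) {
  samples <- validate_samples(samples)
  stage <- function(what, expr) {
    r <- try(expr, silent = TRUE)
    if (inherits(r, "try-error")) {
      stop("pipeline stage '", what, "' failed: ",
           attr(r, "condition")$message)
    }
    r
  }
  map <- stage("map", map_snps_to_genes(snps, genes, upstream, downstream))
  db <- stage("filter_pathways", filter_pathways(db, min_genes, max_genes))
  db <- stage("restrict_db",
              suppressMessages(restrict_db_to_genes(db,
                                                    names(map$gene2snp))))
  units <- if (pool_loci) pool_shared_loci(map) else NULL

  snp_res <- stage("assoc", assoc_scan(genotypes, samples, covariates,
                                       maf_min))
  retained <- snp_res$snp_id[!snp_res$excluded]
  message(length(retained), "/", nrow(snp_res), " SNPs retained after the ",
          "MAF and convergence filters")

  if (run_heterogeneity && nlevels(samples$study) > 1) {
    pathway_snps <- intersect(retained,
                              unique(unlist(map$gene2snp[
                                unique(unlist(db$sets))],
                                use.names = FALSE)))
    meta <- stage("heterogeneity",
                  snp_meta_scan(genotypes, samples, pathway_snps))
    filt <- flag_and_filter(meta, map, het_threshold)
    message(length(filt$removed), " SNP(s) removed by the heterogeneity ",
            "filter; ", length(filt$dropped_genes), " gene(s) lost all SNPs")
  } else {
    meta <- NULL
    filt <- list(removed = character(0), map = map,
                 dropped_genes = character(0))
  }

  units_post <- if (pool_loci) pool_shared_loci(filt$map) else NULL
  if (pool_loci) {
    db_pre <- db_to_units(db, units)
    db_post <- db_to_units(db, units_post)
  } else {
    db_pre <- db
    db_post <- db
  }

  run_state <- function(state_map, state_db, state_units, snp_keep) {
    engine <- permutation_gene_p(genotypes, samples, state_map, covariates,
                                 B = B, seed = seed, units = state_units,
                                 snp_keep = snp_keep)
    gsea <- gsea_scan(state_db, engine, weight_p)
    artp <- artp_all(state_db, engine)
    ns_g <- normalize_scan(stats::setNames(gsea$table$es,
                                           gsea$table$set_id),
                           gsea$perm_es)
    ns_a <- normalize_scan(stats::setNames(artp$table$minp,
                                           artp$table$set_id),
                           artp$minp_perm, neg_log = TRUE)
    list(engine = engine, gsea = gsea, artp = artp,
         fdr_gsea = fdr_table(ns_g$ns, ns_g$ns_perm),
         fdr_artp = fdr_table(ns_a$ns, ns_a$ns_perm),
         ns_gsea = ns_g$ns, ns_artp = ns_a$ns)
  }
  pre <- stage("enrichment_prefilter",
               run_state(map, db_pre, units, retained))
  post <- stage("enrichment_postfilter",
                run_state(filt$map, db_post,
                          units_post, setdiff(retained, filt$removed)))

  gene_res <- best_snp_per_gene(filt$map, snp_res, units = units_post)

  merge_col <- function(tab, ids, col) tab[[col]][match(ids, tab$set_id)]
  ids <- post$gsea$table$set_id
  report <- data.frame(
    set_id = ids,
    source = db$source[ids],
    n_genes = post$gsea$table$n_genes,
    n_genes_with_data = post$gsea$table$n_genes_with_data,
    n_genes_with_data_pre = merge_col(pre$gsea$table, ids,
                                      "n_genes_with_data"),
    p_gsea = post$gsea$table$p_gsea,
    p_gsea_pre = merge_col(pre$gsea$table, ids, "p_gsea"),
    fdr_gsea = unname(post$fdr_gsea[ids]),
    p_artp = merge_col(post$artp$table, ids, "p_artp"),
    p_artp_pre = merge_col(pre$artp$table, ids, "p_artp"),
    fdr_artp = unname(post$fdr_artp[ids]),
    stringsAsFactors = FALSE)
  rownames(report) <- NULL
  manifest <- list(seed = seed, B = B, covariates = covariates,
                   upstream = upstream, downstream = downstream,
                   maf_min = maf_min, het_threshold = het_threshold,
                   weight_p = weight_p, pool_loci = pool_loci,
                   n_snps = ncol(genotypes), n_samples = nrow(samples),
                   n_pathways = length(db$sets),
                   n_snps_retained = length(retained),
                   n_snps_removed_heterogeneity = length(filt$removed))
  structure(list(report = report, snp_results = snp_res,
                 gene_results = gene_res, meta = meta,
                 removed_snps = filt$removed, pre = pre, post = post,
                 manifest = manifest),
            class = "pathway_run")
}

#' @export
print.pathway_run <- function(x, ...) {
  cat("pathway_run:", nrow(x$report), "pathways, B =", x$manifest$B,
      ", seed =", x$manifest$seed, "\n")
  top <- x$report[order(pmin(x$report$p_gsea, x$report$p_artp)), ]
  print(utils::head(top[, c("set_id", "n_genes", "p_gsea", "fdr_gsea",
                            "p_artp", "fdr_artp")], 5))
  invisible(x)
}

#' @keywords internal
#' Recast a pathway_db from gene ids to locus-unit ids.
db_to_units <- function(db, units) {
  sets <- lapply(db$sets, function(g) {
    sort(unique(stats::na.omit(units$gene2unit[g])))
  })
  keep <- lengths(sets) > 0
  pathway_db(sets[keep], db$source[keep])
}

#' Packaged gene-level summary tables from a published bladder-cancer GWAS
#'
#' Gene-level best-SNP summary statistics (per-allele OR, 95% CI, 1-df
#' trend p-value, control MAF, SNP counts and ranks) for four pathway
#' groups from a published five-study case-control bladder-cancer GWAS:
#' aromatic amine metabolism, NAD metabolism, clathrin-mediated vesicle
#' pathways, and the mitotic metaphase/anaphase transition. Used for
#' worked-example tests of the table utilities.
#'
#' @param which One of "aa_metabolism", "nad_metabolism",
#'   "clathrin_vesicle", "mitotic_transition".
#' @return data.frame with columns `gene, pathway, n_snps, best_snp,
#'   snp_rank, maf, or_, ci_low, ci_high, p`.
#' @export
load_gene_summary <- function(which = c("aa_metabolism", "nad_metabolism",
                                        "clathrin_vesicle",
                                        "mitotic_transition")) {
  which <- match.arg(which)
  path <- system.file("extdata", "gene_summaries",
                      paste0(which, ".tsv"), package = "pathgwas",
                      mustWork = TRUE)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Count table rows satisfying a predicate
#'
#' Worked-example helper: applies a one-argument predicate function to a
#' summary table and counts rows where it holds.
#'
#' @param fixture data.frame (e.g. from [load_gene_summary()]).
#' @param predicate Function taking the data.frame and returning a logical
#'   vector over rows; it may only use existing columns.
#' @return Integer count.
#' @export
table_filter_count <- function(fixture, predicate) {
  v <- predicate(fixture)
  if (!is.logical(v) || length(v) != nrow(fixture)) {
    stop("predicate must return one logical per row")
  }
  sum(v, na.rm = TRUE)
}

#' Write a pathway run's result tables to a directory
#'
#' Emits `report.tsv` (Table-1-shaped joint report with pre-filter
#' companion columns), `snp_results.tsv`, `gene_results.tsv`,
#' `heterogeneity.tsv` (when computed), `removed_snps.txt` and
#' `manifest.json`.
#'
#' @param run A `pathway_run`.
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_run_results <- function(run, outdir) {
  stopifnot(inherits(run, "pathway_run"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) utils::write.table(df, file.path(outdir, f),
                                           sep = "\t", quote = FALSE,
                                           row.names = FALSE)
  wt(run$report, "report.tsv")
  wt(run$snp_results, "snp_results.tsv")
  wt(run$gene_results, "gene_results.tsv")
  if (!is.null(run$meta)) wt(run$meta, "heterogeneity.tsv")
  writeLines(run$removed_snps, file.path(outdir, "removed_snps.txt"))
  jsonlite::write_json(run$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(outdir)
}
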