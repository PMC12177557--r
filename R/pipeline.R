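#' Pipeline configuration
#'
#' Collects every threshold of the discovery chain in one validated object.
#' Inputs come either from a \code{\link{sim_config}} (synthetic mode) or
#' from files (VCF genotypes, counts TSV, gene BED, covariates TSV,
#' optional trait TSV and QTL interval TSV).
#'
#' @param sim a \code{\link{sim_config}} for synthetic mode, or NULL.
#' @param vcf,counts,gene_bed,covariates,trait,qtl input file paths (file
#'   mode; ignored when \code{sim} is given).
#' @param maf_min,miss_max variant QC thresholds.
#' @param prune_window,prune_r2,prune_step LD-pruning parameters (0.5 Mb
#'   window, r^2 cutoff 0.7, sidestep 10 retained SNPs).
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @param min_frac cpm-filter retention fraction (strict "> 35%").
#' @param sw_alpha,sw_max_removals Shapiro-Wilk outlier-screen parameters.
#' @param eqtl_gap,eqtl_min_snps,eqtl_ext region-calling parameters (split at
#'   gaps >= 1 Mb, keep >= 3 SNPs, extend 0.5 Mb).
#' @param cis_window cis/trans window (1 Mb, inclusive).
#' @param hotspot_min_genes,tophot_min hotspot / top-hotspot minima.
#' @param coloc_p1,coloc_p2,coloc_p12,coloc_prior_sd,coloc_coverage
#'   colocalization priors, effect prior SD and credible-set coverage.
#' @param run_coloc_stage,run_pcit_stage stage toggles.
#' @param seed integer seed for any stage randomness.
#' @return validated list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(sim = NULL, vcf = NULL, counts = NULL,
                            gene_bed = NULL, covariates = NULL,
                            trait = NULL, qtl = NULL,
                            maf_min = 0.05, miss_max = 0.10,
                            prune_window = 5e5, prune_r2 = 0.7,
                            prune_step = 10L,
                            alpha = 0.05, min_frac = 0.35,
                            sw_alpha = 0.01, sw_max_removals = 3L,
                            eqtl_gap = 1e6, eqtl_min_snps = 3L,
                            eqtl_ext = 5e5, cis_window = 1e6,
                            hotspot_min_genes = 10L, tophot_min = 10L,
                            coloc_p1 = 1e-4, coloc_p2 = 1e-4,
                            coloc_p12 = 1e-5, coloc_prior_sd = 0.15,
                            coloc_coverage = 0.95,
                            run_coloc_stage = TRUE, run_pcit_stage = TRUE,
                            seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(sim) && (is.null(vcf) || is.null(counts)))
    stop("either a sim_config or input files (vcf + counts) are required")
  stopifnot(alpha > 0, alpha < 1, maf_min > 0, maf_min <= 0.5,
            miss_max >= 0, miss_max < 1, prune_window > 0,
            prune_r2 > 0, prune_r2 <= 1, prune_step >= 1,
            min_frac >= 0, min_frac < 1, eqtl_gap > 0, eqtl_min_snps >= 1,
            eqtl_ext >= 0, cis_window >= 0, hotspot_min_genes >= 1,
            tophot_min >= 1, coloc_coverage > 0, coloc_coverage < 1)
  coloc_priors(coloc_p1, coloc_p2, coloc_p12)  # validates the prior triple
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full eQTL discovery pipeline
#'
#' Stage order: simulate/read inputs; TMM normalization, zero masking, cpm
#' filter and Shapiro-Wilk outlier screen; variant QC; LD pruning and the
#' Bonferroni threshold on independent SNPs; per-gene mixed-model eGWAS (one
#' GRM eigendecomposition shared by all genes); eQTL region calling with
#' cis/trans labels; hotspot and top-hotspot detection; QTL/cis-eQTL overlap
#' plus colocalization when a trait is available; PCIT co-expression over
#' the largest hotspot's target genes. Every stage writes its TSV artifact
#' plus a JSON run log of all resolved parameters; a rerun with the same
#' config reproduces identical outputs.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir output directory (created if needed).
#' @return (invisibly) a list of the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # --- inputs -----------------------------------------------------------
  truth <- NULL; trait <- NULL; qtl <- NULL
  if (!is.null(config$sim)) {
    inp <- stage("simulate", {
      geno <- simulate_genotypes(config$sim)
      ex <- simulate_expression(geno, config$sim)
      list(geno = geno, ex = ex)
    })
    geno <- inp$geno
    counts <- inp$ex$counts
    genes <- inp$ex$genes
    covar <- inp$ex$covariates
    truth <- inp$ex$truth
    write_genotypes_vcf(geno, file.path(out_dir, "genotypes.vcf"))
    write_matrix_tsv(counts, file.path(out_dir, "counts.tsv"), "gene")
    write_gene_bed(genes, file.path(out_dir, "genes.bed"))
    write_tsv(covar, file.path(out_dir, "covariates.tsv"))
    if (nrow(truth$cis))
      write_tsv(truth$cis, file.path(out_dir, "truth_cis.tsv"))
    if (nrow(truth$hotspots))
      write_tsv(truth$hotspots, file.path(out_dir, "truth_hotspots.tsv"))
  } else {
    geno <- stage("read_genotypes", read_genotypes(config$vcf))
    counts <- stage("read_counts", read_counts(config$counts))
    genes <- stage("read_genes", read_gene_bed(config$gene_bed))
    covar <- if (!is.null(config$covariates)) {
      cv <- read_tsv(config$covariates)
      as.data.frame(lapply(cv, factor))
    } else NULL
    if (!is.null(config$trait)) trait <- read_tsv(config$trait)
    if (!is.null(config$qtl)) qtl <- read_tsv(config$qtl)
  }

  # --- expression preparation ------------------------------------------
  norm <- stage("normalize",
                normalize_counts(counts, min_frac = config$min_frac,
                                 alpha_sw = config$sw_alpha,
                                 max_removals = config$sw_max_removals))
  write_matrix_tsv(norm$log2cpm, file.path(out_dir, "log2cpm.tsv"), "gene")
  write_tsv(norm$filter, file.path(out_dir, "filter_report.tsv"))

  # --- genotype QC, pruning, threshold ---------------------------------
  qc <- stage("variant_qc",
              filter_variants(geno, config$maf_min, config$miss_max))
  write_tsv(qc$report, file.path(out_dir, "variant_qc.tsv"))
  geno <- qc$geno
  indep <- stage("ld_prune",
                 ld_prune(geno, config$prune_window, config$prune_r2,
                          config$prune_step))
  writeLines(indep, file.path(out_dir, "independent_snps.txt"))
  pstar <- bonferroni_threshold(config$alpha, length(indep))

  # --- eGWAS ------------------------------------------------------------
  G <- stage("grm", compute_grm(geno))
  eg <- grm_decompose(G)
  rot <- rotate_genotypes(eg, geno)
  expr_genes <- intersect(rownames(norm$log2cpm), genes$id)
  scans <- stage("egwas", {
    res <- vector("list", length(expr_genes))
    names(res) <- expr_genes
    for (g in expr_genes) {
      y <- norm$log2cpm[g, ]
      if (anyNA(y)) {
        fit <- tryCatch(fit_null(y, covar, G), error = function(e) NULL)
        sc <- if (is.null(fit)) NULL else scan_snps(fit, geno, pstar)
      } else {
        fit <- fit_null(y, covar, eg)
        sc <- scan_snps(fit, rot, pstar)
      }
      if (!is.null(sc)) { sc$gene <- g; res[[g]] <- sc }
    }
    data.table::rbindlist(res[!vapply(res, is.null, logical(1))])
  })
  scans <- as.data.frame(scans)
  sig <- scans[scans$significant, , drop = FALSE]
  write_tsv(sig, file.path(out_dir, "significant_associations.tsv"))

  # --- eQTL regions, labels, hotspots ----------------------------------
  regions <- stage("eqtl_regions", {
    per_gene <- split(sig, sig$gene)
    out <- lapply(per_gene, call_regions, gap = config$eqtl_gap,
                  min_snps = config$eqtl_min_snps, ext = config$eqtl_ext)
    out <- do.call(rbind, out)
    if (is.null(out) || !nrow(out)) out
    else label_regions(out, genes, config$cis_window)
  })
  if (!is.null(regions) && nrow(regions)) {
    rownames(regions) <- NULL
    write_tsv(regions, file.path(out_dir, "eqtl_regions.tsv"))
  }
  hot <- stage("hotspots",
               detect_hotspots(sig, genes, config$hotspot_min_genes,
                               config$cis_window))
  write_tsv(hot, file.path(out_dir, "hotspots.tsv"))
  tophot <- if (!is.null(regions) && nrow(regions))
    detect_top_hotspots(regions, config$tophot_min)
  else detect_top_hotspots(call_regions(sig[0, ])[0, ])
  write_tsv(tophot, file.path(out_dir, "top_hotspots.tsv"))

  # --- trait GWAS, overlap, colocalization -----------------------------
  coloc_res <- NULL; overlaps <- NULL
  if (config$run_coloc_stage) {
    if (is.null(trait) && !is.null(config$sim) &&
        nrow(truth$cis)) {
      # synthetic trait sharing the first planted cis variant
      tv <- truth$cis$variant[1]
      trait_y <- simulate_trait(geno, tv, effect = 0.6, h2 = 0.2,
                                seed = config$seed + 7L)
      gfit <- fit_null(trait_y, covar, eg)
      tscan <- scan_snps(gfit, rot, pstar)
      tgene <- truth$cis$gene[1]
      if (tgene %in% scans$gene) {
        gs <- scans[scans$gene == tgene, , drop = FALSE]
        vpos <- geno$variants$pos[match(tv, geno$variants$id)]
        coloc_res <- stage("coloc", run_coloc(
          tscan, gs,
          region = list(chrom = geno$variants$chrom[1],
                        start = max(1, vpos - 1e6), end = vpos + 1e6),
          priors = coloc_priors(config$coloc_p1, config$coloc_p2,
                                config$coloc_p12),
          prior_sd = config$coloc_prior_sd,
          coverage = config$coloc_coverage))
        write_tsv(data.frame(t(coloc_res$pp), nsnps = coloc_res$nsnps),
                  file.path(out_dir, "coloc.tsv"))
        write_tsv(data.frame(variant = coloc_res$credible_set),
                  file.path(out_dir, "coloc_credible_set.tsv"))
      }
    }
    if (!is.null(qtl) && !is.null(regions) && nrow(regions)) {
      cisr <- regions[regions$label == "cis", , drop = FALSE]
      ov <- overlap_intervals(qtl, cisr)
      overlaps <- data.frame(qtl = qtl[ov$qtl_row, , drop = FALSE],
                             region = cisr[ov$region_row, , drop = FALSE])
      write_tsv(overlaps, file.path(out_dir, "qtl_overlaps.tsv"))
    }
  }

  # --- PCIT on the largest hotspot's targets ---------------------------
  pcit_res <- NULL
  if (config$run_pcit_stage && nrow(hot)) {
    top1 <- hot[which.max(hot$n_genes), ]
    tg <- strsplit(top1$genes, ",")[[1]]
    tg <- intersect(tg, rownames(norm$log2cpm))
    if (length(tg) >= 3) {
      pcit_res <- stage("pcit", pcit_network(norm$log2cpm[tg, , drop = FALSE]))
      write_tsv(pcit_res$edges, file.path(out_dir, "pcit_edges.tsv"))
    }
  }

  log <- list(package_version = as.character(utils::packageVersion("bloodeqtl")),
              seed = config$seed,
              n_samples = nrow(geno$dosage),
              n_variants_post_qc = ncol(geno$dosage),
              n_independent = length(indep),
              bonferroni_p = pstar,
              n_genes_tested = length(expr_genes),
              n_significant = nrow(sig),
              n_regions = if (is.null(regions)) 0L else nrow(regions),
              n_hotspots = nrow(hot),
              n_top_hotspots = nrow(tophot),
              params = config[!vapply(config, is.null, logical(1)) &
                                !names(config) %in% "sim"])
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(list(geno = geno, norm = norm, threshold = pstar,
                 scans = scans, significant = sig, regions = regions,
                 hotspots = hot, top_hotspots = tophot, truth = truth,
                 coloc = coloc_res, overlaps = overlaps, pcit = pcit_res))
}
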