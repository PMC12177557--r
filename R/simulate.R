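#' Simulation configuration
#'
#' Bundles all parameters of the synthetic-data generator: an LD-structured
#' genotype panel built as mosaics of founder haplotypes, negative-binomial
#' RNA-seq counts with planted cis effects, trans hotspots and a polygenic
#' background, and quantitative traits sharing causal variants with gene
#' expression.
#'
#' @param n_samples number of diploid individuals (default 255, a typical
#'   commercial-population eGWAS cohort).
#' @param n_variants number of biallelic SNPs to emit (before the MAF filter).
#' @param chrom_length chromosome length in bp over which variants are placed.
#' @param n_founder_haplotypes number of founder haplotypes in the mosaic
#'   model; must be >= 2. Fewer founders means stronger, blockier LD.
#' @param block_length_mean mean length (bp) of the exponentially distributed
#'   founder-copy blocks; controls LD decay.
#' @param founder_ld_length decay length (bp) of the founder panel's
#'   allele-pattern autocorrelation; sites much closer than this share
#'   founder patterns and so sit in high r^2.
#' @param maf_min variants whose realized sample MAF falls below this are
#'   dropped (default 0.05, matching the usual post-imputation filter).
#' @param n_genes number of genes.
#' @param cis_fraction fraction of genes given a planted cis-acting variant
#'   within 1 Mb of the TSS (default 0.35).
#' @param cis_beta_sd SD of planted cis allele-substitution effects, in log2
#'   expression units per alt allele.
#' @param hotspot_spec list of hotspot descriptors, each a list/vector with
#'   elements \code{variant} (variant index in the emitted panel),
#'   \code{n_targets} (number of regulated genes, >= 10 to be recoverable as a
#'   hotspot) and \code{beta} (log2 effect on every target).
#' @param cis_spec optional list of explicit cis plantings, each a list with
#'   elements \code{gene} (gene index), \code{variant} (variant index; must
#'   lie within 1 Mb of that gene's TSS, which the generator arranges by
#'   moving the TSS next to the variant) and \code{beta} (log2 effect).
#'   Genes named here are excluded from the random \code{cis_fraction} draw.
#' @param h2_polygenic share of the Gaussian log2-scale biological variance
#'   attributed to the polygenic (GRM-correlated) term; in [0, 1).
#' @param libsize_range length-2 range of per-sample library sizes (reads).
#' @param nb_dispersion negative-binomial dispersion (edgeR convention;
#'   variance = mu + dispersion * mu^2).
#' @param resid_sd residual biological SD on the log2 scale (per gene/sample),
#'   on top of counting noise.
#' @param miss_rate rate at which genotype calls are masked to missing, to
#'   exercise the missingness filter.
#' @param seed integer seed; all outputs are deterministic given the seed.
#' @return an object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_samples = 255L,
                       n_variants = 5000L,
                       chrom_length = 5e7,
                       n_founder_haplotypes = 12L,
                       block_length_mean = 2e5,
                       founder_ld_length = 5e5,
                       maf_min = 0.05,
                       n_genes = 200L,
                       cis_fraction = 0.35,
                       cis_beta_sd = 0.4,
                       hotspot_spec = list(),
                       cis_spec = list(),
                       h2_polygenic = 0.2,
                       libsize_range = c(14.5e6, 45e6),
                       nb_dispersion = 0.1,
                       resid_sd = 0.5,
                       miss_rate = 0.01,
                       seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_variants = as.integer(n_variants),
              chrom_length = as.numeric(chrom_length),
              n_founder_haplotypes = as.integer(n_founder_haplotypes),
              block_length_mean = as.numeric(block_length_mean),
              founder_ld_length = as.numeric(founder_ld_length),
              maf_min = maf_min, n_genes = as.integer(n_genes),
              cis_fraction = cis_fraction, cis_beta_sd = cis_beta_sd,
              hotspot_spec = hotspot_spec, cis_spec = cis_spec,
              h2_polygenic = h2_polygenic,
              libsize_range = as.numeric(libsize_range),
              nb_dispersion = nb_dispersion, resid_sd = resid_sd,
              miss_rate = miss_rate, seed = as.integer(seed))
  stopifnot(cfg$n_samples > 0, cfg$n_variants > 0, cfg$chrom_length > 0,
            cfg$block_length_mean > 0, cfg$founder_ld_length > 0,
            cfg$n_genes > 0,
            cfg$maf_min > 0, cfg$maf_min <= 0.5,
            cfg$cis_fraction >= 0, cfg$cis_fraction <= 1,
            cfg$h2_polygenic >= 0, cfg$h2_polygenic < 1,
            length(cfg$libsize_range) == 2, all(cfg$libsize_range > 0),
            cfg$nb_dispersion > 0, cfg$resid_sd >= 0,
            cfg$miss_rate >= 0, cfg$miss_rate < 1)
  if (cfg$n_founder_haplotypes < 2)
    stop("n_founder_haplotypes must be >= 2: no polymorphism is possible")
  class(cfg) <- "sim_config"
  cfg
}

#' Construct a genotype matrix object
#'
#' The package-wide genotype container: a samples x variants dosage matrix in
#' \{0, 1, 2, NA\} plus a per-variant table of chrom/pos/id/MAF.
#'
#' @param dosage samples x variants numeric matrix (alt-allele counts).
#' @param variants data.frame with columns \code{id}, \code{chrom}, \code{pos}
#'   (1-based), and optionally \code{ref}, \code{alt}.
#' @return object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(dosage, variants) {
  stopifnot(is.matrix(dosage), nrow(variants) == ncol(dosage),
            all(c("id", "chrom", "pos") %in% names(variants)))
  ok <- dosage %in% c(0, 1, 2) | is.na(dosage)
  if (!all(ok)) stop("dosages must be in {0, 1, 2} or NA")
  colnames(dosage) <- variants$id
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("s%03d", seq_len(nrow(dosage)))
  variants$maf <- variant_maf(dosage)
  structure(list(dosage = dosage, variants = variants,
                 samples = rownames(dosage)),
            class = "genotype_matrix")
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (chrom %s)\n",
              nrow(x$dosage), ncol(x$dosage),
              paste(unique(x$variants$chrom), collapse = ",")))
  invisible(x)
}

# per-variant minor allele frequency on non-missing calls (NaN if all missing)
variant_maf <- function(dosage) {
  p <- colMeans(dosage, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

# founder index per variant for one mosaic haplotype
mosaic_path <- function(pos, chrom_length, n_founders, block_mean) {
  brk <- numeric(0)
  at <- 0
  while (at < chrom_length) {
    at <- at + stats::rexp(1, rate = 1 / block_mean)
    brk <- c(brk, at)
  }
  founders <- sample.int(n_founders, length(brk), replace = TRUE)
  founders[findInterval(pos, c(0, brk[-length(brk)]))]
}

#' Simulate LD-structured genotypes
#'
#' Generates a biallelic SNP panel with blockwise linkage disequilibrium using
#' a mosaic-of-founder-haplotypes model: each diploid individual is the sum of
#' two haplotypes, each a mosaic of the founder haplotypes with exponentially
#' distributed block lengths. Variants whose realized sample MAF falls below
#' \code{cfg$maf_min} are dropped; a fraction \code{cfg$miss_rate} of calls is
#' masked to missing.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return a \code{\link{genotype_matrix}}; variants are position-sorted. The
#'   founder haplotype panel is attached as attribute \code{"founders"}.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_founder_haplotypes < 2)
    stop("n_founder_haplotypes must be >= 2: no polymorphism is possible")
  set.seed(cfg$seed)
  m <- cfg$n_variants
  pos <- sort(sample.int(cfg$chrom_length, m))
  # founder allele frequencies drawn away from the boundaries so realized
  # sample MAF clears maf_min for most variants
  fr <- stats::runif(m, 0.1, 0.9)
  # founder panel with spatially autocorrelated allele patterns: each founder
  # keeps its previous allele with probability exp(-d / founder_ld_length),
  # so nearby sites share founder patterns (high r^2) while distant sites are
  # effectively independent; the individual-level mosaic then propagates this
  # blockwise LD into the sample
  nf <- cfg$n_founder_haplotypes
  H <- matrix(0L, nf, m)
  H[, 1] <- stats::rbinom(nf, 1L, fr[1])
  if (m > 1) {
    q <- exp(-diff(pos) / cfg$founder_ld_length)
    for (i in 2:m) {
      keep <- stats::rbinom(nf, 1L, q[i - 1]) == 1L
      H[, i] <- ifelse(keep, H[, i - 1], stats::rbinom(nf, 1L, fr[i]))
    }
  }
  dos <- matrix(0L, cfg$n_samples, m)
  for (j in seq_len(cfg$n_samples)) {
    f1 <- mosaic_path(pos, cfg$chrom_length, cfg$n_founder_haplotypes,
                      cfg$block_length_mean)
    f2 <- mosaic_path(pos, cfg$chrom_length, cfg$n_founder_haplotypes,
                      cfg$block_length_mean)
    dos[j, ] <- H[cbind(f1, seq_len(m))] + H[cbind(f2, seq_len(m))]
  }
  storage.mode(dos) <- "double"
  if (cfg$miss_rate > 0) {
    nmiss <- stats::rbinom(1, length(dos), cfg$miss_rate)
    if (nmiss > 0) dos[sample.int(length(dos), nmiss)] <- NA_real_
  }
  maf <- variant_maf(dos)
  keep <- !is.nan(maf) & maf >= cfg$maf_min
  dos <- dos[, keep, drop = FALSE]
  pos <- pos[keep]
  rownames(dos) <- sprintf("s%03d", seq_len(cfg$n_samples))
  geno <- genotype_matrix(dos, data.frame(
    id = sprintf("snp%05d", which(keep)), chrom = "1", pos = pos,
    ref = "A", alt = "G", stringsAsFactors = FALSE))
  attr(geno, "founders") <- H[, keep, drop = FALSE]
  geno
}

# lower-triangular factor of a (possibly semi-definite) covariance matrix
cov_factor <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  d <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(d), length(d))
}

# polygenic draw: u ~ N(0, sd2 * G), one column per requested draw
polygenic_draws <- function(Gfac, n_draws, sd2) {
  if (sd2 <= 0) return(matrix(0, nrow(Gfac), n_draws))
  Gfac %*% matrix(stats::rnorm(ncol(Gfac) * n_draws), ncol = n_draws) *
    sqrt(sd2)
}

#' Simulate RNA-seq counts with planted regulatory architecture
#'
#' Gene \eqn{g}, sample \eqn{j} counts are drawn
#' NegBin(mean = L_j/10^6 * 2^eta_gj, dispersion), where the log2-scale linear
#' predictor eta contains the gene's baseline abundance, the planted cis
#' effect, any hotspot effects targeting the gene, sex and batch effects, a
#' polygenic term correlated through the GRM of the simulated genotypes, and a
#' Gaussian residual. Planted cis variants sit within 1 Mb of the gene TSS.
#'
#' @param geno a \code{\link{genotype_matrix}} from
#'   \code{\link{simulate_genotypes}}.
#' @param cfg the same \code{\link{sim_config}}.
#' @param covariates optional data.frame with factors \code{sex} and
#'   \code{batch}, one row per sample; generated (balanced sex, 6 batches)
#'   when NULL.
#' @return list with \code{counts} (genes x samples integer matrix),
#'   \code{genes} (id/chrom/start/end/tss), \code{covariates},
#'   \code{libsize}, and \code{truth} — the truth table with elements
#'   \code{cis} (gene, variant, beta) and \code{hotspots} (variant, beta,
#'   comma-separated target genes).
#' @export
simulate_expression <- function(geno, cfg, covariates = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(cfg, "sim_config"))
  n <- nrow(geno$dosage)
  set.seed(cfg$seed + 1L)
  if (is.null(covariates)) {
    covariates <- data.frame(
      sex = factor(sample(rep_len(c("F", "M"), n))),
      batch = factor(sprintf("b%d", sort(rep_len(1:6, n)))))
  }
  if (nrow(covariates) != n)
    stop("covariate rows must equal genotype sample count")
  for (h in cfg$hotspot_spec) {
    vi <- h[["variant"]]
    if (is.null(vi) || vi < 1 || vi > ncol(geno$dosage))
      stop("hotspot_spec names a variant outside the genotype panel")
  }

  ng <- cfg$n_genes
  tss <- sort(sample.int(cfg$chrom_length, ng))

  X <- geno$dosage
  Ximp <- mean_impute(X)
  pos <- geno$variants$pos

  # explicit cis plantings: relocate the gene TSS beside the named variant so
  # the planted effect is cis by construction
  for (cs in cfg$cis_spec) {
    gi <- as.integer(cs[["gene"]]); vi <- as.integer(cs[["variant"]])
    if (gi < 1 || gi > ng) stop("cis_spec names a gene outside the panel")
    if (vi < 1 || vi > ncol(X))
      stop("cis_spec names a variant outside the genotype panel")
    tss[gi] <- max(1, pos[vi] + sample(-5e4:5e4, 1))
  }
  glen <- sample(2e3:8e4, ng, replace = TRUE)
  genes <- data.frame(id = sprintf("gene%04d", seq_len(ng)), chrom = "1",
                      start = tss, end = pmin(tss + glen, cfg$chrom_length),
                      tss = tss, stringsAsFactors = FALSE)

  mu0 <- stats::rnorm(ng, mean = 5, sd = 1.5)          # baseline log2 cpm
  sex_eff <- stats::rnorm(ng, 0, 0.15)
  batch_eff <- matrix(stats::rnorm(ng * nlevels(covariates$batch), 0, 0.15),
                      nrow = ng)

  # planted cis variants
  n_cis <- round(cfg$cis_fraction * ng)
  fixed_cis <- vapply(cfg$cis_spec, function(cs) as.integer(cs[["gene"]]),
                      integer(1))
  cis_genes <- sort(sample(setdiff(seq_len(ng), fixed_cis),
                           min(n_cis, ng - length(fixed_cis))))
  cis_tab <- data.frame(gene = character(0), variant = character(0),
                        beta = numeric(0), stringsAsFactors = FALSE)
  beta_mat <- matrix(0, ng, ncol(X))                    # gene x variant effects
  for (cs in cfg$cis_spec) {
    gi <- as.integer(cs[["gene"]]); vi <- as.integer(cs[["variant"]])
    b <- as.numeric(cs[["beta"]])
    beta_mat[gi, vi] <- beta_mat[gi, vi] + b
    cis_tab <- rbind(cis_tab, data.frame(
      gene = genes$id[gi], variant = geno$variants$id[vi], beta = b))
  }
  for (g in cis_genes) {
    near <- which(abs(pos - tss[g]) <= 1e6)
    if (!length(near)) next
    v <- sample(near, 1)
    b <- stats::rnorm(1, 0, cfg$cis_beta_sd)
    beta_mat[g, v] <- beta_mat[g, v] + b
    cis_tab <- rbind(cis_tab, data.frame(
      gene = genes$id[g], variant = geno$variants$id[v], beta = b))
  }
  # planted trans hotspots
  hot_tab <- data.frame(variant = character(0), beta = numeric(0),
                        targets = character(0), stringsAsFactors = FALSE)
  for (h in cfg$hotspot_spec) {
    v <- as.integer(h[["variant"]])
    k <- as.integer(h[["n_targets"]])
    b <- as.numeric(h[["beta"]])
    # target genes drawn away from the hotspot so the planted links are trans
    far <- which(abs(tss - pos[v]) > 2e6)
    tg <- sample(far, min(k, length(far)))
    beta_mat[tg, v] <- beta_mat[tg, v] + b
    hot_tab <- rbind(hot_tab, data.frame(
      variant = geno$variants$id[v], beta = b,
      targets = paste(genes$id[tg], collapse = ",")))
  }

  sig_u2 <- if (cfg$h2_polygenic > 0)
    cfg$resid_sd^2 * cfg$h2_polygenic / (1 - cfg$h2_polygenic) else 0
  Gfac <- if (sig_u2 > 0) cov_factor(compute_grm(geno)) else NULL
  U <- if (is.null(Gfac)) matrix(0, n, ng)
       else polygenic_draws(Gfac, ng, sig_u2)

  libsize <- round(stats::runif(n, cfg$libsize_range[1], cfg$libsize_range[2]))
  Z <- stats::model.matrix(~ 0 + batch, covariates)
  eta <- matrix(mu0, ng, n) +
    beta_mat %*% t(Ximp) +
    outer(sex_eff, as.numeric(covariates$sex == levels(covariates$sex)[2])) +
    batch_eff %*% t(Z) +
    t(U) +
    matrix(stats::rnorm(ng * n, 0, cfg$resid_sd), ng, n)
  mu <- sweep(2^eta, 2, libsize / 1e6, `*`)
  counts <- matrix(stats::rnbinom(ng * n, mu = mu, size = 1 / cfg$nb_dispersion),
                   ng, n, dimnames = list(genes$id, rownames(geno$dosage)))
  list(counts = counts, genes = genes, covariates = covariates,
       libsize = libsize,
       truth = list(cis = cis_tab, hotspots = hot_tab))
}

#' Simulate a quantitative trait with an optional shared causal variant
#'
#' trait = effect * dosage + polygenic term (variance h2 through the GRM) +
#' iid residual (variance 1 - h2), then standardized to mean 0, variance 1.
#'
#' @param geno a \code{\link{genotype_matrix}}.
#' @param shared_variant variant id (or index) of the causal variant; NULL for
#'   a purely polygenic/null trait.
#' @param effect allele-substitution effect in (pre-standardization) trait SD
#'   units.
#' @param h2 polygenic heritability in [0, 1).
#' @param seed integer seed.
#' @return numeric trait vector, named by sample.
#' @export
simulate_trait <- function(geno, shared_variant = NULL, effect = 0,
                           h2 = 0, seed = 1L) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (h2 < 0 || h2 >= 1) stop("h2 must be in [0, 1)")
  set.seed(as.integer(seed))
  n <- nrow(geno$dosage)
  g <- numeric(n)
  if (!is.null(shared_variant) && effect != 0) {
    v <- if (is.character(shared_variant))
      match(shared_variant, geno$variants$id) else as.integer(shared_variant)
    if (is.na(v) || v < 1 || v > ncol(geno$dosage))
      stop("shared_variant not found in genotype panel")
    g <- effect * mean_impute(geno$dosage[, v, drop = FALSE])[, 1]
  }
  u <- if (h2 > 0)
    drop(polygenic_draws(cov_factor(compute_grm(geno)), 1, h2)) else 0
  e <- stats::rnorm(n, 0, sqrt(1 - h2))
  y <- g + u + e
  y <- (y - mean(y)) / stats::sd(y)
  names(y) <- rownames(geno$dosage)
  y
}

#' Effect size for a target fraction of variance explained
#'
#' Returns the allele-substitution effect beta such that a variant with allele
#' frequency \code{p} explains fraction \code{pve} of the total phenotypic
#' variance, given the variance \code{noise_var} of everything else:
#' beta^2 * 2p(1-p) = pve/(1-pve) * noise_var.
#'
#' @param pve target proportion of variance explained, in (0, 1).
#' @param p alt-allele frequency.
#' @param noise_var variance of the phenotype net of this variant.
#' @return beta (positive root).
#' @export
beta_for_pve <- function(pve, p, noise_var = 1) {
  stopifnot(pve > 0, pve < 1, p > 0, p < 1, noise_var > 0)
  sqrt(pve / (1 - pve) * noise_var / (2 * p * (1 - p)))
}
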