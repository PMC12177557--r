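# numerically stable log-sum-exp and log-diff-exp
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
logdiffexp <- function(a, b) {
  # log(exp(a) - exp(b)), a >= b
  if (b > a) return(NaN)
  if (b == -Inf) return(a)
  a + log1p(-exp(b - a))
}

#' Wakefield approximate Bayes factor (log scale)
#'
#' For a single-SNP association with estimate beta and standard error se,
#' under an N(0, W) effect prior: with V = se^2, r = W / (V + W) and
#' z = beta / se, log ABF = 0.5 * log(1 - r) + z^2 * r / 2 (association vs
#' null). Vectorized over SNPs.
#'
#' @param beta,se effect estimates and standard errors (se > 0).
#' @param prior_sd sqrt(W); the default 0.15 is the quantitative-trait
#'   convention for phenotypes standardized to unit SD.
#' @return numeric vector of log ABFs.
#' @export
log_abf <- function(beta, se, prior_sd = 0.15) {
  if (any(se <= 0)) stop("se must be > 0")
  if (prior_sd < 0) stop("prior_sd must be >= 0")
  W <- prior_sd^2
  V <- se^2
  r <- W / (V + W)
  z <- beta / se
  0.5 * log1p(-r) + z^2 * r / 2
}

#' Colocalization priors
#'
#' @param p1,p2 per-SNP prior probability of causality for trait 1 / trait 2
#'   (defaults 1e-4).
#' @param p12 per-SNP prior of shared causality (default 1e-5).
#' @return validated list of class \code{coloc_priors}.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  stopifnot(p12 > 0, p12 <= p1, p12 <= p2, p1 < 1, p2 < 1)
  structure(list(p1 = p1, p2 = p2, p12 = p12), class = "coloc_priors")
}

#' Five-hypothesis colocalization posteriors
#'
#' Given per-SNP log approximate Bayes factors for two traits over the same
#' region (aligned by variant id), computes the posterior probabilities of
#' H0 (no causal variant), H1 (trait-1 only), H2 (trait-2 only), H3 (two
#' distinct causal variants) and H4 (one shared causal variant). With
#' S1 = logsumexp(l1), S2 = logsumexp(l2), S12 = logsumexp(l1 + l2), the
#' log evidence terms are H0: 0; H1: log p1 + S1; H2: log p2 + S2;
#' H3: log p1 + log p2 + log(exp(S1 + S2) - exp(S12)); H4: log p12 + S12.
#' All sums are kept in log space.
#'
#' @param l1,l2 log ABF vectors for the two traits, same variants in the
#'   same order (inner-join upstream).
#' @param priors a \code{\link{coloc_priors}}.
#' @param snp_id optional variant ids; \code{snp_pos} optional positions used
#'   only to break credible-set ties.
#' @param coverage credible-set coverage (default 0.95).
#' @return object of class \code{coloc_result}: \code{pp} (named PP.H0..
#'   PP.H4, summing to 1), \code{snp_h4} (per-SNP posterior of being the
#'   shared causal variant under H4), \code{credible_set}, \code{nsnps}.
#' @export
coloc_posteriors <- function(l1, l2, priors = coloc_priors(),
                             snp_id = NULL, snp_pos = NULL,
                             coverage = 0.95) {
  stopifnot(inherits(priors, "coloc_priors"))
  if (length(l1) != length(l2)) stop("l1 and l2 must be aligned")
  if (!length(l1)) stop("zero shared SNPs after join")
  S1 <- logsumexp(l1)
  S2 <- logsumexp(l2)
  S12 <- logsumexp(l1 + l2)
  h3 <- if (length(l1) == 1) -Inf else {
    d <- logdiffexp(S1 + S2, S12)
    if (is.nan(d)) {
      warning("S12 exceeded S1 + S2 numerically; H3 evidence floored")
      -Inf
    } else d
  }
  ev <- c(H0 = 0,
          H1 = log(priors$p1) + S1,
          H2 = log(priors$p2) + S2,
          H3 = log(priors$p1) + log(priors$p2) + h3,
          H4 = log(priors$p12) + S12)
  pp <- exp(ev - logsumexp(ev))
  pp <- pp / sum(pp)
  names(pp) <- paste0("PP.", names(ev))
  l12 <- l1 + l2
  snp_h4 <- exp(l12 - logsumexp(l12))
  if (!is.null(snp_id)) names(snp_h4) <- snp_id
  cs <- credible_set(snp_h4, coverage = coverage, pos = snp_pos)
  structure(list(pp = pp, snp_h4 = snp_h4, credible_set = cs,
                 nsnps = length(l1)), class = "coloc_result")
}

#' @exportS3Method base::print
print.coloc_result <- function(x, ...) {
  cat(sprintf("coloc_result over %d SNPs\n", x$nsnps))
  print(round(x$pp, 4))
  cat(sprintf("95%% credible set: %d variant(s)\n", length(x$credible_set)))
  invisible(x)
}

#' Credible set of shared causal variants
#'
#' Sorts the per-SNP posterior descending and takes the smallest prefix whose
#' cumulative posterior reaches \code{coverage}; posterior ties are broken by
#' genomic position (then by input order).
#'
#' @param posterior per-SNP posterior vector (sums to 1 within 1e-8).
#' @param coverage target coverage in (0, 1) (default 0.95).
#' @param pos optional positions for tie-breaking.
#' @return ids (names) of the selected variants, or their indices when the
#'   vector is unnamed.
#' @export
credible_set <- function(posterior, coverage = 0.95, pos = NULL) {
  if (coverage <= 0 || coverage >= 1) stop("coverage must be in (0, 1)")
  if (abs(sum(posterior) - 1) > 1e-8)
    stop("posterior must sum to 1")
  ord <- if (is.null(pos)) order(-posterior, seq_along(posterior))
         else order(-posterior, pos)
  k <- which(cumsum(posterior[ord]) >= coverage)[1]
  sel <- ord[seq_len(k)]
  if (!is.null(names(posterior))) names(posterior)[sel] else sel
}

#' Colocalize two association scans over a region
#'
#' Inner-joins two scan outputs (from \code{\link{scan_snps}}) by variant id,
#' optionally restricted to a region, computes Wakefield log ABFs for both
#' and the five-hypothesis posteriors.
#'
#' @param scan1,scan2 data.frames with columns id, chrom, pos, beta, se.
#' @param region optional list(chrom, start, end) restricting the join.
#' @param priors a \code{\link{coloc_priors}}.
#' @param prior_sd effect prior SD passed to \code{\link{log_abf}}.
#' @param coverage credible-set coverage.
#' @return a \code{coloc_result}.
#' @export
run_coloc <- function(scan1, scan2, region = NULL, priors = coloc_priors(),
                      prior_sd = 0.15, coverage = 0.95) {
  s1 <- scan1[!scan1$degenerate %in% TRUE & !is.na(scan1$se), , drop = FALSE]
  s2 <- scan2[!scan2$degenerate %in% TRUE & !is.na(scan2$se), , drop = FALSE]
  if (!is.null(region)) {
    s1 <- s1[s1$chrom == region$chrom & s1$pos >= region$start &
               s1$pos <= region$end, , drop = FALSE]
  }
  j <- merge(s1[, c("id", "chrom", "pos", "beta", "se")],
             s2[, c("id", "beta", "se")], by = "id",
             suffixes = c("_1", "_2"))
  if (!nrow(j)) stop("zero shared SNPs after join")
  j <- j[order(j$pos), , drop = FALSE]
  coloc_posteriors(log_abf(j$beta_1, j$se_1, prior_sd),
                   log_abf(j$beta_2, j$se_2, prior_sd),
                   priors = priors, snp_id = j$id, snp_pos = j$pos,
                   coverage = coverage)
}
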