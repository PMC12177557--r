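#' Variant-level quality control
#'
#' Drops variants with minor allele frequency below \code{maf_min} (computed
#' on non-missing calls) or with a missing-call fraction strictly above
#' \code{miss_max}. Order is preserved; a per-variant drop reason is reported.
#' A variant with every call missing is dropped with reason "all-missing".
#'
#' @param geno a \code{\link{genotype_matrix}}.
#' @param maf_min MAF cutoff (default 0.05; "below 5%" is strict).
#' @param miss_max missingness cutoff (default 0.10; "more than 10%" is
#'   strict, so exactly 10% missing is kept).
#' @return list: \code{geno} (filtered \code{genotype_matrix}) and
#'   \code{report} (data.frame: id, maf, miss_frac, kept, reason).
#' @export
filter_variants <- function(geno, maf_min = 0.05, miss_max = 0.10) {
  stopifnot(inherits(geno, "genotype_matrix"))
  X <- geno$dosage
  miss <- colMeans(is.na(X))
  maf <- variant_maf(X)
  reason <- rep(NA_character_, ncol(X))
  reason[miss > miss_max] <- "high_missing"
  reason[is.nan(maf)] <- "all-missing"
  reason[!is.nan(maf) & maf < maf_min & is.na(reason)] <- "low_maf"
  kept <- is.na(reason)
  rep_df <- data.frame(id = geno$variants$id, maf = maf, miss_frac = miss,
                       kept = kept, reason = reason)
  out <- genotype_matrix(X[, kept, drop = FALSE],
                         geno$variants[kept, , drop = FALSE])
  list(geno = out, report = rep_df)
}

#' Squared-correlation LD between two dosage vectors
#'
#' r^2 = squared Pearson correlation of mean-imputed dosages (composite LD on
#' unphased data). Returns 0 if either vector is constant.
#'
#' @param x,y dosage vectors (NAs mean-imputed).
#' @return r^2 in [0, 1].
#' @export
ld_r2 <- function(x, y) {
  x[is.na(x)] <- mean(x, na.rm = TRUE)
  y[is.na(y)] <- mean(y, na.rm = TRUE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)^2
}

# drop the losing member of a high-LD pair: later position, tie -> lower MAF
prune_loser <- function(i, j, pos, maf) {
  if (pos[i] != pos[j]) return(if (pos[i] < pos[j]) j else i)
  if (maf[i] <= maf[j]) i else j
}

#' LD pruning to an independent variant set
#'
#' Greedy windowed pruning: within each sliding window spanning \code{window}
#' bp, pairwise r^2 between mean-imputed dosage vectors is computed and, when
#' r^2 > \code{r2_max}, the later-positioned variant is removed (ties by
#' position remove the lower-MAF variant); the window start then advances by
#' \code{step} retained variants. A final ascending sweep over retained
#' variants enforces the postcondition that no surviving pair within
#' \code{window} bp has r^2 > \code{r2_max} (stepped windows alone can skip
#' pairs straddling frame boundaries); the sweep also makes pruning
#' idempotent.
#'
#' @param geno a \code{\link{genotype_matrix}}, position-sorted per
#'   chromosome.
#' @param window window span in bp (default 500000).
#' @param r2_max LD cutoff (default 0.7; removal requires r^2 strictly
#'   above it).
#' @param step number of retained variants by which the window start advances
#'   (default 10).
#' @return character vector of surviving variant ids.
#' @export
ld_prune <- function(geno, window = 5e5, r2_max = 0.7, step = 10L) {
  stopifnot(inherits(geno, "genotype_matrix"),
            window > 0, r2_max > 0, r2_max <= 1, step >= 1)
  v <- geno$variants
  for (ch in unique(v$chrom))
    if (is.unsorted(v$pos[v$chrom == ch]))
      stop("variants must be position-sorted within each chromosome")
  keep <- rep(TRUE, nrow(v))
  X <- mean_impute(geno$dosage)
  maf <- v$maf
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    pos <- v$pos[idx]
    kp <- keep[idx]
    start <- 1L
    repeat {
      ret <- which(kp)
      ret <- ret[ret >= start]
      if (!length(ret)) break
      s <- ret[1]
      win <- ret[pos[ret] <= pos[s] + window]
      if (length(win) > 1) {
        # iterate until no pair in this frame exceeds the cutoff
        repeat {
          act <- win[kp[win]]
          hit <- FALSE
          if (length(act) > 1) {
            for (a in seq_len(length(act) - 1)) {
              for (b in seq((a + 1), length(act))) {
                i <- act[a]; j <- act[b]
                if (!kp[i] || !kp[j]) next
                if (ld_r2(X[, idx[i]], X[, idx[j]]) > r2_max) {
                  kp[prune_loser(i, j, pos, maf[idx])] <- FALSE
                  hit <- TRUE
                }
              }
            }
          }
          if (!hit) break
        }
      }
      ret <- which(kp)
      ret <- ret[ret >= start]
      if (length(ret) <= step) break
      start <- ret[step + 1L]
    }
    # final guarantee sweep: ascending over retained variants
    ret <- which(kp)
    for (a in seq_along(ret)) {
      i <- ret[a]
      if (!kp[i]) next
      for (j in ret[-seq_len(a)]) {
        if (!kp[j] || pos[j] - pos[i] > window) next
        if (ld_r2(X[, idx[i]], X[, idx[j]]) > r2_max)
          kp[prune_loser(i, j, pos, maf[idx])] <- FALSE
        if (!kp[i]) break
      }
    }
    keep[idx] <- kp
  }
  v$id[keep]
}

#' Bonferroni threshold on independent tests
#'
#' Per-test p-value threshold alpha / n_independent, where n_independent is
#' the number of LD-independent variants (e.g. from \code{\link{ld_prune}}).
#' With alpha = 0.05 and 118,571 independent SNPs this is 4.217e-7.
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param n_independent number of independent tests, >= 1.
#' @return per-test p-value threshold.
#' @export
bonferroni_threshold <- function(alpha, n_independent) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  if (n_independent < 1) stop("n_independent must be >= 1")
  alpha / n_independent
}
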