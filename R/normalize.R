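#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values scaling factors (Robinson & Oshlack): the
#' reference sample is the column whose 75th-percentile cpm is closest to the
#' mean 75th percentile; per-gene log2 ratios (M) and mean log2 abundances (A)
#' are computed over genes positive in both columns, the 30% M tails and 5% A
#' tails are trimmed, and each factor is 2 to the inverse-variance-weighted
#' mean of the remaining M values, with weights from the binomial delta
#' method. Factors are rescaled to geometric mean 1. Computation is delegated
#' to edgeR's TMM implementation of the same estimator.
#'
#' @param counts non-negative integer matrix, genes x samples (>= 2 samples).
#' @return named numeric vector of per-sample factors, geometric mean 1.
#' @export
tmm_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("TMM needs at least 2 samples")
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  zero <- colSums(counts, na.rm = TRUE) == 0
  if (any(zero))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[zero], collapse = ", "))
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  names(f) <- colnames(counts)
  f
}

#' Log2 counts-per-million with zero masking
#'
#' Raw zero counts are set to missing (NA) before transformation — a zero read
#' count is treated as unobserved expression, not as -Inf. For nonzero
#' counts, cpm = count / (library size x TMM factor) x 10^6 and the value is
#' log2(cpm + prior); the default prior is 0 because zeros are already masked.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param factors per-sample TMM factors from \code{\link{tmm_factors}}.
#' @param prior pseudo-count added on the cpm scale before log2 (default 0).
#' @return matrix of log2-cpm values with NA where the raw count was 0 (or
#'   missing). Effective library sizes are attached as attribute
#'   \code{"eff_libsize"}.
#' @export
log_cpm <- function(counts, factors, prior = 0) {
  counts <- as.matrix(counts)
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  stopifnot(length(factors) == ncol(counts))
  lib <- colSums(counts, na.rm = TRUE)
  eff <- lib * factors
  x <- counts
  x[x == 0] <- NA
  out <- log2(sweep(x, 2, eff / 1e6, `/`) + prior)
  attr(out, "eff_libsize") <- eff
  out
}

#' Expression-level filter
#'
#' Retains a gene iff strictly more than \code{min_frac} of its non-missing
#' sample values exceed the cpm threshold t = 10 / (minimum library size in
#' millions). With a minimum library of ~14.5 M reads this resolves to the
#' familiar cpm > 0.69; the rule, not the constant, is what generalizes.
#'
#' @param log2cpm matrix from \code{\link{log_cpm}} (NA = masked zero).
#' @param min_lib_millions minimum library size across samples, in millions
#'   of reads.
#' @param min_frac retention fraction; the comparison is strict (default
#'   0.35, i.e. "more than 35% of the samples").
#' @return list with \code{retained} (character vector of gene ids) and
#'   \code{report} (data.frame: gene, pass_frac, retained).
#' @export
filter_genes <- function(log2cpm, min_lib_millions, min_frac = 0.35) {
  if (!is.matrix(log2cpm) || nrow(log2cpm) == 0 || ncol(log2cpm) == 0)
    stop("empty expression matrix")
  stopifnot(min_lib_millions > 0)
  t_log2 <- log2(10 / min_lib_millions)
  pass_frac <- apply(log2cpm, 1, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) 0 else mean(v > t_log2)
  })
  retained <- pass_frac > min_frac
  genes <- rownames(log2cpm)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(log2cpm)))
  list(retained = genes[retained],
       report = data.frame(gene = genes, pass_frac = unname(pass_frac),
                           retained = unname(retained)))
}

#' Leave-one-out Shapiro-Wilk outlier removal
#'
#' If the Shapiro-Wilk p-value of the gene's non-missing values is already >=
#' \code{alpha_sw}, the vector is returned unchanged. Otherwise the test is
#' repeated leaving each sample out in turn; if the best leave-one-out p-value
#' reaches \code{alpha_sw}, that sample is masked to NA and the procedure
#' repeats, up to \code{max_removals} times.
#'
#' @param x numeric vector (one gene's normalized values), possibly with NAs.
#' @param alpha_sw normality alpha (default 0.01).
#' @param max_removals cap on removed samples per gene (default 3).
#' @return list with \code{values} (x with outliers masked) and
#'   \code{removed} (indices/names of masked samples).
#' @export
remove_outliers <- function(x, alpha_sw = 0.01, max_removals = 3L) {
  idx_ok <- which(!is.na(x))
  if (length(idx_ok) < 8)
    stop("need at least 8 non-missing values for the Shapiro-Wilk screen")
  removed <- integer(0)
  for (iter in seq_len(max_removals)) {
    obs <- which(!is.na(x))
    p0 <- stats::shapiro.test(x[obs])$p.value
    if (p0 >= alpha_sw) break
    loo <- vapply(seq_along(obs), function(i)
      stats::shapiro.test(x[obs[-i]])$p.value, numeric(1))
    best <- which.max(loo)
    if (loo[best] < alpha_sw) break    # removal would not restore normality
    removed <- c(removed, obs[best])
    x[obs[best]] <- NA
  }
  nm <- names(x)
  list(values = x,
       removed = if (!is.null(nm)) nm[removed] else removed)
}

#' Normalize and filter a count matrix
#'
#' Convenience wrapper chaining \code{\link{tmm_factors}},
#' \code{\link{log_cpm}}, \code{\link{filter_genes}} and per-gene
#' \code{\link{remove_outliers}} in the standard order (normalize, mask zeros,
#' filter low expression, then screen normality).
#'
#' @param counts genes x samples count matrix.
#' @param min_frac retention fraction for the cpm filter.
#' @param alpha_sw,max_removals outlier-screen parameters; set
#'   \code{alpha_sw = 0} to skip the screen.
#' @param prior cpm pseudo-count for \code{\link{log_cpm}}.
#' @return list: \code{log2cpm} (retained genes, outliers masked),
#'   \code{factors}, \code{filter} (report from \code{filter_genes}),
#'   \code{outliers} (per-gene removed sample ids), \code{min_lib_millions}.
#' @export
normalize_counts <- function(counts, min_frac = 0.35, alpha_sw = 0.01,
                             max_removals = 3L, prior = 0) {
  f <- tmm_factors(counts)
  lc <- log_cpm(counts, f, prior = prior)
  lmin <- min(colSums(counts, na.rm = TRUE)) / 1e6
  flt <- filter_genes(lc, lmin, min_frac = min_frac)
  lc <- lc[flt$retained, , drop = FALSE]
  outliers <- list()
  if (alpha_sw > 0 && ncol(lc) >= 8) {
    for (g in rownames(lc)) {
      if (sum(!is.na(lc[g, ])) < 8) next
      r <- remove_outliers(lc[g, ], alpha_sw = alpha_sw,
                           max_removals = max_removals)
      lc[g, ] <- r$values
      if (length(r$removed)) outliers[[g]] <- r$removed
    }
  }
  list(log2cpm = lc, factors = f, filter = flt$report, outliers = outliers,
       min_lib_millions = lmin)
}
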