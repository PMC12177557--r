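# per-variant mean imputation of missing dosages
mean_impute <- function(X) {
  miss <- is.na(X)
  if (!any(miss)) return(X)
  mu <- colMeans(X, na.rm = TRUE)
  X[miss] <- mu[col(X)[miss]]
  X
}

#' Genomic relationship matrix
#'
#' Yang et al. (GCTA) estimator:
#' G_jk = (1/m) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i)),
#' with p_i the sample alt-allele frequency. Missing dosages are mean-imputed
#' per variant; monomorphic variants are excluded from m.
#'
#' @param geno a \code{\link{genotype_matrix}} (or samples x variants dosage
#'   matrix) with >= 2 polymorphic variants.
#' @return n x n symmetric matrix with attribute \code{"m"} (variant count
#'   used).
#' @export
compute_grm <- function(geno) {
  X <- if (inherits(geno, "genotype_matrix")) geno$dosage else as.matrix(geno)
  X <- mean_impute(X)
  p <- colMeans(X) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all variants are monomorphic")
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  W <- sweep(X, 2, 2 * p, `-`)
  W <- sweep(W, 2, sqrt(2 * p * (1 - p)), `/`)
  G <- tcrossprod(W) / ncol(W)
  attr(G, "m") <- ncol(W)
  G
}

#' Eigendecomposition of a GRM for reuse across phenotypes
#'
#' One decomposition serves every null fit and scan on the same sample set;
#' scanning many genes therefore triggers a single decomposition.
#'
#' @param G symmetric GRM from \code{\link{compute_grm}}.
#' @return object of class \code{grm_eigen}: \code{U} (eigenvectors),
#'   \code{d} (eigenvalues, floored at 0), \code{samples}.
#' @export
grm_decompose <- function(G) {
  if (max(abs(G - t(G))) > 1e-10) stop("GRM must be symmetric")
  e <- eigen(G, symmetric = TRUE)
  structure(list(U = e$vectors, d = pmax(e$values, 0),
                 samples = rownames(G), n = nrow(G)),
            class = "grm_eigen")
}

# REML profile log-likelihood pieces at a given lambda (rotated basis)
reml_at_lambda <- function(lam, yr, Xr, d) {
  n <- length(yr); p <- ncol(Xr)
  w <- lam * d + (1 - lam)
  Xw <- Xr / sqrt(w); yw <- yr / sqrt(w)
  XtX <- crossprod(Xw)
  R <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  beta <- backsolve(R, forwardsolve(t(R), crossprod(Xw, yw)))
  rss <- sum((yw - Xw %*% beta)^2)
  s2 <- rss / (n - p)
  ll <- -0.5 * ((n - p) * log(s2) + sum(log(w)) +
                  2 * sum(log(diag(R))) + (n - p))
  list(ll = ll, beta = drop(beta), s2 = s2, w = w, Xw = Xw, yw = yw, R = R)
}

#' Fit the null (no-SNP) linear mixed model by REML
#'
#' Model y = X beta + g + e with g ~ N(0, G sigma_g^2), e ~ N(0, I sigma_e^2).
#' After rotating into the GRM eigenbasis the covariance is diagonal in the
#' variance ratio lambda = sigma_g^2 / (sigma_g^2 + sigma_e^2), which is
#' estimated by 1-D REML optimization (bracket tolerance 1e-6, lambda clamped
#' to [0, 1 - 1e-6]); beta follows by generalized least squares at the
#' optimum. When sigma_g^2 is estimated at the zero boundary the model
#' reduces to ordinary least squares.
#'
#' @param y phenotype vector (NAs allowed: casewise deletion).
#' @param covariates data.frame of fixed effects (or NULL for intercept
#'   only); an intercept is always added.
#' @param G GRM matrix or a \code{\link{grm_decompose}} object for the full
#'   sample set. If y has missing values and a matrix is supplied, the
#'   subset GRM is decomposed; a pre-made decomposition requires complete y.
#' @return object of class \code{null_fit}: beta, sigma_g2, sigma_e2, lambda,
#'   loglik, plus the rotated design retained for \code{\link{scan_snps}}.
#' @export
fit_null <- function(y, covariates, G) {
  obs <- which(!is.na(y))
  if (length(obs) < 10) stop("need >= 10 non-missing phenotype values")
  if (stats::sd(y[obs]) == 0) stop("phenotype has zero variance")
  X <- if (is.null(covariates)) matrix(1, length(y), 1,
                                       dimnames = list(NULL, "(Intercept)"))
       else stats::model.matrix(~ ., data = covariates)
  qrX <- qr(X[obs, , drop = FALSE])
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("covariate matrix is rank-deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  if (inherits(G, "grm_eigen")) {
    if (length(obs) != G$n)
      stop("precomputed grm_eigen requires complete phenotype; ",
           "pass the GRM matrix instead")
    eg <- G
  } else {
    eg <- grm_decompose(G[obs, obs, drop = FALSE])
  }
  yr <- drop(crossprod(eg$U, y[obs]))
  Xr <- crossprod(eg$U, X[obs, , drop = FALSE])
  obj <- function(l) {
    f <- reml_at_lambda(l, yr, Xr, eg$d)
    if (is.null(f)) -Inf else f$ll
  }
  opt <- stats::optimize(obj, c(0, 1 - 1e-6), maximum = TRUE, tol = 1e-6)
  # the optimum can sit on a boundary optimize() never samples exactly
  cand <- c(opt$maximum, 0, 1 - 1e-6)
  lls <- vapply(cand, obj, numeric(1))
  lam <- cand[which.max(lls)]
  fit <- reml_at_lambda(lam, yr, Xr, eg$d)
  s2_tot <- fit$s2
  structure(list(beta = stats::setNames(fit$beta, colnames(X)),
                 sigma_g2 = lam * s2_tot, sigma_e2 = (1 - lam) * s2_tot,
                 lambda = lam, loglik = fit$ll,
                 eigen = eg, obs = obs, w = fit$w,
                 Xw = fit$Xw, yw = fit$yw,
                 n = length(obs), p = ncol(X)),
            class = "null_fit")
}

#' @exportS3Method base::print
print.null_fit <- function(x, ...) {
  cat(sprintf(
    "null_fit: n=%d, lambda=%.3f (sigma_g2=%.4g, sigma_e2=%.4g), logLik=%.2f\n",
    x$n, x$lambda, x$sigma_g2, x$sigma_e2, x$loglik))
  invisible(x)
}

#' Rotate a genotype panel into a GRM eigenbasis
#'
#' Precomputes U' S for reuse when many phenotypes are scanned against the
#' same panel and sample set.
#'
#' @param eg a \code{\link{grm_decompose}} object.
#' @param geno a \code{\link{genotype_matrix}}.
#' @return object of class \code{rotated_genotypes}.
#' @export
rotate_genotypes <- function(eg, geno) {
  stopifnot(inherits(eg, "grm_eigen"), inherits(geno, "genotype_matrix"))
  S <- mean_impute(geno$dosage)
  structure(list(Sr = crossprod(eg$U, S), af = colMeans(S) / 2,
                 sds = apply(S, 2, stats::sd),
                 variants = geno$variants, n = nrow(S)),
            class = "rotated_genotypes")
}

#' Single-SNP mixed-model association scan
#'
#' For each variant, the allele-substitution effect and its standard error
#' are estimated by generalized least squares in the GRM eigenbasis with the
#' variance ratio lambda held at the null REML estimate; the residual scale
#' is re-profiled per SNP with the SNP in the model (divisor n - p - 1), so
#' that with an identity GRM the scan collapses exactly to ordinary
#' least-squares regression. Two-sided Wald p-values use the normal
#' reference. Variants constant in the analysis subset are emitted with
#' p = 1 and a degenerate flag.
#'
#' @param null a \code{\link{fit_null}} object.
#' @param geno a \code{\link{genotype_matrix}} on the same samples, or a
#'   \code{\link{rotate_genotypes}} object built from the same
#'   decomposition (only valid when the null fit used all samples).
#' @param threshold significance threshold p* (records flagged
#'   \code{significant} when p < p*); default NULL flags nothing.
#' @return data.frame: id, chrom, pos, af, n, beta, se, p, significant,
#'   degenerate.
#' @export
scan_snps <- function(null, geno, threshold = NULL) {
  stopifnot(inherits(null, "null_fit"))
  if (inherits(geno, "rotated_genotypes")) {
    if (null$n != geno$n)
      stop("rotated genotypes require a null fit on the full sample set")
    Sr <- geno$Sr; variants <- geno$variants
    sds <- geno$sds; af <- geno$af
  } else {
    stopifnot(inherits(geno, "genotype_matrix"))
    S <- mean_impute(geno$dosage[null$obs, , drop = FALSE])
    sds <- apply(S, 2, stats::sd)
    af <- colMeans(S) / 2
    Sr <- crossprod(null$eigen$U, S)
    variants <- geno$variants
  }
  n <- null$n; p <- null$p
  Sw <- Sr / sqrt(null$w)
  # project out the fixed effects in the whitened basis
  cf <- backsolve(chol(crossprod(null$Xw)),
                  forwardsolve(t(chol(crossprod(null$Xw))),
                               crossprod(null$Xw, Sw)))
  Sperp <- Sw - null$Xw %*% cf
  yres <- null$yw - null$Xw %*% null$beta
  ss <- colSums(Sperp^2)
  sy <- drop(crossprod(Sperp, yres))
  rss0 <- sum(yres^2)
  degen <- sds == 0 | ss < 1e-12
  beta <- ifelse(degen, NA_real_, sy / ss)
  rss1 <- pmax(rss0 - ifelse(degen, 0, beta^2 * ss), 0)
  s2 <- rss1 / (n - p - 1)
  se <- ifelse(degen, NA_real_, sqrt(s2 / ss))
  z <- beta / se
  pval <- ifelse(degen, 1, 2 * stats::pnorm(-abs(z)))
  out <- data.frame(id = variants$id, chrom = variants$chrom,
                    pos = variants$pos, af = af, n = n,
                    beta = beta, se = se, p = pval,
                    degenerate = degen, row.names = NULL)
  out$significant <- if (is.null(threshold)) FALSE else (!degen & pval < threshold)
  out
}
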