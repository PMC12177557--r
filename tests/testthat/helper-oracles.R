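# Independent brute-force oracles. These re-derive each rule directly from
# its definition, deliberately avoiding the package's code paths.

# --- TMM: direct evaluation of the trimmed weighted-mean formula -----------
oracle_tmm <- function(counts) {
  lib <- colSums(counts)
  cpm <- t(t(counts) / lib) * 1e6
  uq <- apply(cpm, 2, stats::quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(k) {
    x <- counts[, k]; r <- counts[, ref]
    keep <- x > 0 & r > 0
    x <- x[keep]; r <- r[keep]
    Nk <- lib[k]; Nr <- lib[ref]
    M <- log2((x / Nk) / (r / Nr))
    A <- 0.5 * log2((x / Nk) * (r / Nr))
    w <- (Nk - x) / (Nk * x) + (Nr - r) / (Nr * r)
    n <- length(M)
    loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep2)) return(1)
    2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

# --- eQTL region grouping: independent gap scan ----------------------------
oracle_regions <- function(pos, p, gap = 1e6, min_snps = 3, ext = 5e5) {
  o <- order(pos)
  pos <- pos[o]; p <- p[o]
  groups <- list(); cur <- 1
  if (length(pos) > 1) {
    for (i in 2:length(pos)) {
      if (pos[i] - pos[i - 1] >= gap) { groups <- c(groups, list(cur)); cur <- c() }
      cur <- c(cur, i)
    }
  }
  groups <- c(groups, list(cur))
  out <- NULL
  for (g in groups) {
    if (length(g) < min_snps) next
    pp <- p[g]; po <- pos[g]
    best <- which(pp == min(pp))
    best <- best[which.min(po[best])]
    out <- rbind(out, data.frame(start = min(po), end = max(po),
                                 ext_start = max(1, min(po) - ext),
                                 ext_end = max(po) + ext,
                                 n_snps = length(g),
                                 top_pos = po[best], top_p = pp[best]))
  }
  out
}

# --- interval overlap: quadratic loop over closed intervals ----------------
oracle_overlap <- function(qtl, regions) {
  out <- NULL
  for (i in seq_len(nrow(qtl))) for (j in seq_len(nrow(regions))) {
    if (qtl$chrom[i] == regions$chrom[j] &&
        qtl$start[i] <= regions$ext_end[j] &&
        regions$ext_start[j] <= qtl$end[i])
      out <- rbind(out, data.frame(qtl_row = i, region_row = j))
  }
  if (is.null(out)) data.frame(qtl_row = integer(0), region_row = integer(0))
  else out
}

# --- LD prune audit: exhaustive pair check over survivors ------------------
oracle_prune_violations <- function(geno, ids, window = 5e5, r2_max = 0.7) {
  idx <- match(ids, geno$variants$id)
  pos <- geno$variants$pos[idx]
  chrom <- geno$variants$chrom[idx]
  X <- geno$dosage[, idx, drop = FALSE]
  n_viol <- 0
  for (i in seq_along(idx)) {
    j <- which(chrom == chrom[i] & pos > pos[i] & pos - pos[i] <= window)
    for (k in j) if (ld_r2(X[, i], X[, k]) > r2_max) n_viol <- n_viol + 1
  }
  n_viol
}

# --- exact per-SNP joint REML refit (1-D grid + optimize over lambda) ------
oracle_joint_reml_p <- function(y, X, G, s) {
  Xs <- cbind(X, s)
  e <- eigen(G, symmetric = TRUE)
  U <- e$vectors; d <- pmax(e$values, 0)
  yr <- drop(crossprod(U, y)); Xr <- crossprod(U, Xs)
  n <- length(yr); p <- ncol(Xr)
  ll <- function(l) {
    w <- l * d + (1 - l)
    Xw <- Xr / sqrt(w); yw <- yr / sqrt(w)
    fit <- stats::lm.fit(Xw, yw)
    s2 <- sum(fit$residuals^2) / (n - p)
    -0.5 * ((n - p) * log(s2) + sum(log(w)) +
              determinant(crossprod(Xw), logarithm = TRUE)$modulus[1] +
              (n - p))
  }
  opt <- stats::optimize(ll, c(0, 1 - 1e-6), maximum = TRUE, tol = 1e-8)
  lam <- opt$maximum
  if (ll(0) > opt$objective) lam <- 0
  w <- lam * d + (1 - lam)
  Xw <- Xr / sqrt(w); yw <- yr / sqrt(w)
  XtXi <- solve(crossprod(Xw))
  beta <- XtXi %*% crossprod(Xw, yw)
  s2 <- sum((yw - Xw %*% beta)^2) / (n - p)
  se <- sqrt(s2 * XtXi[p, p])
  2 * stats::pnorm(-abs(beta[p] / se))
}

# --- PCIT: literal triple loop over trios ----------------------------------
oracle_pcit_kept <- function(data) {
  C <- stats::cor(t(data))
  nv <- nrow(C)
  kept <- matrix(TRUE, nv, nv); diag(kept) <- FALSE
  pc <- function(a, b, c) (C[a, b] - C[a, c] * C[b, c]) /
    sqrt((1 - C[a, c]^2) * (1 - C[b, c]^2))
  for (x in 1:(nv - 1)) for (y in (x + 1):nv) {
    all_below <- TRUE
    any_z <- FALSE
    for (z in seq_len(nv)[-c(x, y)]) {
      any_z <- TRUE
      terms <- c()
      if (abs(C[x, y]) >= 1e-12) terms <- c(terms, pc(x, y, z) / C[x, y])
      if (abs(C[x, z]) >= 1e-12) terms <- c(terms, pc(x, z, y) / C[x, z])
      if (abs(C[y, z]) >= 1e-12) terms <- c(terms, pc(y, z, x) / C[y, z])
      eps <- if (length(terms)) mean(terms) else 0
      if (!(abs(C[x, y]) < abs(eps * C[x, z]) &&
            abs(C[x, y]) < abs(eps * C[y, z]))) all_below <- FALSE
    }
    if (any_z && all_below) kept[x, y] <- kept[y, x] <- FALSE
  }
  kept
}

# --- colocalization: enumeration over causal configurations ---------------
# Works in plain (non-log) space; only valid for small regions/moderate ABFs.
oracle_coloc_evidence <- function(l1, l2, p1, p2, p12) {
  b1 <- exp(l1); b2 <- exp(l2)
  N <- length(b1)
  h0 <- 1
  h1 <- p1 * sum(b1)
  h2 <- p2 * sum(b2)
  h3 <- 0
  for (i in seq_len(N)) for (j in seq_len(N)) if (i != j)
    h3 <- h3 + p1 * p2 * b1[i] * b2[j]
  h4 <- p12 * sum(b1 * b2)
  c(H0 = h0, H1 = h1, H2 = h2, H3 = h3, H4 = h4)
}

# --- credible set: minimal-prefix search by exhaustive sorting -------------
oracle_credible_size <- function(post, coverage = 0.95) {
  sp <- sort(post, decreasing = TRUE)
  min(which(cumsum(sp) >= coverage))
}

# --- GRM: element-wise double loop ----------------------------------------
oracle_grm <- function(X) {
  p <- colMeans(X) / 2
  keep <- p > 0 & p < 1
  X <- X[, keep, drop = FALSE]; p <- p[keep]
  n <- nrow(X); m <- ncol(X)
  G <- matrix(0, n, n)
  for (j in 1:n) for (k in 1:n) {
    G[j, k] <- sum((X[j, ] - 2 * p) * (X[k, ] - 2 * p) /
                     (2 * p * (1 - p))) / m
  }
  G
}

# small LD-structured panel for reuse in tests
small_panel <- function(n = 80, m = 120, seed = 42, chrom_length = 5e6, ...) {
  cfg <- sim_config(n_samples = n, n_variants = m,
                    chrom_length = chrom_length, n_genes = 10, seed = seed,
                    ...)
  simulate_genotypes(cfg)
}
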