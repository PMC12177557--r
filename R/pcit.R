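#' PCIT co-expression network
#'
#' Partial Correlation and Information Theory edge selection (Reverter &
#' Chan 2008). All pairwise Pearson correlations are computed
#' (pairwise-complete observations); for every trio (x, y, z) the
#' first-order partial correlations, e.g.
#' r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2)),
#' give the trio's information-theory tolerance
#' eps_xyz = (r_xy.z / r_xy + r_xz.y / r_xz + r_yz.x / r_yz) / 3.
#' Edge (x, y) is removed iff for EVERY third variable z both
#' |r_xy| < |eps_xyz * r_xz| and |r_xy| < |eps_xyz * r_yz|; otherwise kept.
#' Ratios whose denominator has |r| < 1e-12 are skipped from the trio
#' average.
#'
#' @param data numeric matrix, variables x samples (>= 3 variables, >= 5
#'   samples). Traits can be appended as extra rows.
#' @return object of class \code{pcit_network}: \code{nodes}, \code{cor}
#'   (full correlation matrix), \code{kept} (logical symmetric mask),
#'   \code{edges} (long data.frame: var1, var2, r, kept).
#' @export
pcit_network <- function(data) {
  data <- as.matrix(data)
  nv <- nrow(data)
  if (nv < 3) stop("PCIT needs at least 3 variables")
  if (ncol(data) < 5) stop("PCIT needs at least 5 samples")
  nodes <- rownames(data)
  if (is.null(nodes)) nodes <- sprintf("v%d", seq_len(nv))
  sds <- apply(data, 1, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sds) | sds == 0))
    stop("zero-variance variable(s): ",
         paste(nodes[!is.finite(sds) | sds == 0], collapse = ", "))
  C <- stats::cor(t(data), use = "pairwise.complete.obs")
  off <- abs(C[upper.tri(C)])
  if (any(off >= 1 - 1e-12))
    stop("|r| = 1 between distinct variables: partial correlations undefined")
  kept <- matrix(TRUE, nv, nv)
  diag(kept) <- FALSE
  for (x in seq_len(nv - 1)) {
    for (y in seq((x + 1), nv)) {
      z <- setdiff(seq_len(nv), c(x, y))
      rxy <- C[x, y]; rxz <- C[x, z]; ryz <- C[y, z]
      den <- sqrt((1 - rxz^2) * (1 - ryz^2))
      p_xy <- (rxy - rxz * ryz) / den
      p_xz <- (rxz - rxy * ryz) / sqrt((1 - rxy^2) * (1 - ryz^2))
      p_yz <- (ryz - rxy * rxz) / sqrt((1 - rxy^2) * (1 - rxz^2))
      eps <- vapply(seq_along(z), function(k) {
        terms <- c(if (abs(rxy) >= 1e-12) p_xy[k] / rxy,
                   if (abs(rxz[k]) >= 1e-12) p_xz[k] / rxz[k],
                   if (abs(ryz[k]) >= 1e-12) p_yz[k] / ryz[k])
        if (!length(terms)) 0 else mean(terms)
      }, numeric(1))
      rem <- all(abs(rxy) < abs(eps * rxz) & abs(rxy) < abs(eps * ryz))
      if (rem) kept[x, y] <- kept[y, x] <- FALSE
    }
  }
  pairs <- which(upper.tri(C), arr.ind = TRUE)
  edges <- data.frame(var1 = nodes[pairs[, 1]], var2 = nodes[pairs[, 2]],
                      r = C[pairs], kept = kept[pairs],
                      stringsAsFactors = FALSE)
  dimnames(C) <- dimnames(kept) <- list(nodes, nodes)
  structure(list(nodes = nodes, cor = C, kept = kept, edges = edges),
            class = "pcit_network")
}

#' @exportS3Method base::print
print.pcit_network <- function(x, ...) {
  cat(sprintf("pcit_network: %d nodes, %d/%d edges kept\n",
              length(x$nodes), sum(x$edges$kept), nrow(x$edges)))
  invisible(x)
}
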