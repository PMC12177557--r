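#' Call eQTL regions for one gene
#'
#' Groups the gene's significant variants into regions by splitting the
#' position-sorted list at any inter-SNP gap >= \code{gap} ("less than 1 Mb
#' apart" means a gap of exactly 1 Mb splits), discards clusters with fewer
#' than \code{min_snps} members, and extends survivors by \code{ext} bp on
#' each side (floored at position 1, capped at \code{chrom_length} when
#' given). The top variant is the member with the smallest p-value, ties
#' broken by smallest position.
#'
#' @param records data.frame of significant associations for ONE gene:
#'   columns \code{gene}, \code{id}, \code{chrom}, \code{pos}, \code{p};
#'   position-sorted within chromosome.
#' @param gap split distance in bp (default 1e6).
#' @param min_snps minimum members per retained region (default 3).
#' @param ext extension in bp on each side (default 5e5).
#' @param chrom_length optional named vector of chromosome lengths.
#' @return data.frame of regions: gene, chrom, start, end (core), ext_start,
#'   ext_end, n_snps, top_id, top_pos, top_p.
#' @export
call_regions <- function(records, gap = 1e6, min_snps = 3L, ext = 5e5,
                         chrom_length = NULL) {
  if (length(unique(records$gene)) > 1)
    stop("call_regions operates on a single gene's records")
  out <- list()
  for (ch in unique(records$chrom)) {
    r <- records[records$chrom == ch, , drop = FALSE]
    r <- r[order(r$pos), , drop = FALSE]
    cl <- cumsum(c(1, diff(r$pos) >= gap))
    for (k in unique(cl)) {
      m <- r[cl == k, , drop = FALSE]
      if (nrow(m) < min_snps) next
      top <- m[order(m$p, m$pos), ][1, ]
      cap <- if (!is.null(chrom_length) && ch %in% names(chrom_length))
        chrom_length[[ch]] else Inf
      out[[length(out) + 1]] <- data.frame(
        gene = m$gene[1], chrom = ch,
        start = min(m$pos), end = max(m$pos),
        ext_start = max(1, min(m$pos) - ext),
        ext_end = min(cap, max(m$pos) + ext),
        n_snps = nrow(m), top_id = top$id, top_pos = top$pos, top_p = top$p,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      ext_start = numeric(0), ext_end = numeric(0),
                      n_snps = integer(0), top_id = character(0),
                      top_pos = numeric(0), top_p = numeric(0)))
  do.call(rbind, out)
}

#' Classify a variant as cis or trans to a gene
#'
#' cis iff the variant lies on the gene's chromosome and its distance to the
#' nearest gene-body boundary is <= \code{window} bp (distance 0 inside the
#' gene; the 1 Mb boundary is inclusive); otherwise trans.
#'
#' @param variant_chrom,variant_pos variant coordinates (vectorized).
#' @param gene_chrom,gene_start,gene_end gene interval (1-based inclusive).
#' @param window cis window in bp (default 1e6).
#' @return character vector "cis"/"trans".
#' @export
classify_cis_trans <- function(variant_chrom, variant_pos,
                               gene_chrom, gene_start, gene_end,
                               window = 1e6) {
  d <- pmax(gene_start - variant_pos, variant_pos - gene_end, 0)
  ifelse(variant_chrom == gene_chrom & d <= window, "cis", "trans")
}

#' Label eQTL regions cis or trans
#'
#' A region is cis when ANY of its member significant SNPs is cis to the
#' gene; implemented on the core interval (the hull of member SNPs): some
#' member is within the window iff the core interval comes within
#' \code{window} of the gene body.
#'
#' @param regions data.frame from \code{\link{call_regions}}.
#' @param genes data.frame: id, chrom, start, end.
#' @param window cis window in bp.
#' @return \code{regions} with a \code{label} column.
#' @export
label_regions <- function(regions, genes, window = 1e6) {
  gi <- match(regions$gene, genes$id)
  if (anyNA(gi)) stop("region gene(s) missing from gene table")
  gs <- genes$start[gi]; ge <- genes$end[gi]; gc <- genes$chrom[gi]
  # nearest approach of the core interval to the gene body
  d <- pmax(gs - regions$end, regions$start - ge, 0)
  regions$label <- ifelse(regions$chrom == gc & d <= window, "cis", "trans")
  regions
}

#' Detect trans-regulatory hotspots
#'
#' A variant associated with the expression of at least \code{min_genes}
#' distinct genes is a hotspot. The cis flag marks hotspots that are cis to
#' at least one of their associated genes.
#'
#' @param records data.frame of significant associations across genes:
#'   columns \code{gene}, \code{id}, \code{chrom}, \code{pos} (deduplicated
#'   per variant-gene pair internally).
#' @param genes optional gene table (id, chrom, start, end) for the cis flag.
#' @param min_genes hotspot threshold (default 10).
#' @param window cis window in bp.
#' @return data.frame: id, chrom, pos, n_genes, genes (comma-separated),
#'   cis_any.
#' @export
detect_hotspots <- function(records, genes = NULL, min_genes = 10L,
                            window = 1e6) {
  empty <- data.frame(id = character(0), chrom = character(0),
                      pos = numeric(0), n_genes = integer(0),
                      genes = character(0), cis_any = logical(0))
  if (!nrow(records)) return(empty)
  records <- records[!duplicated(records[, c("id", "gene")]), , drop = FALSE]
  cnt <- table(records$id)
  hot_ids <- names(cnt)[cnt >= min_genes]
  if (!length(hot_ids)) return(empty)
  out <- do.call(rbind, lapply(hot_ids, function(v) {
    r <- records[records$id == v, , drop = FALSE]
    cis_any <- FALSE
    if (!is.null(genes)) {
      gi <- match(r$gene, genes$id)
      lab <- classify_cis_trans(r$chrom, r$pos, genes$chrom[gi],
                                genes$start[gi], genes$end[gi], window)
      cis_any <- any(lab == "cis")
    }
    data.frame(id = v, chrom = r$chrom[1], pos = r$pos[1],
               n_genes = nrow(r),
               genes = paste(sort(unique(r$gene)), collapse = ","),
               cis_any = cis_any, stringsAsFactors = FALSE)
  }))
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Detect top-hotspots
#'
#' A variant that is the most significantly associated SNP (region top
#' variant, p ties broken by position) of at least \code{min_top} eQTL
#' regions is a top-hotspot.
#'
#' @param regions data.frame from \code{\link{call_regions}} (possibly many
#'   genes, rbind-ed), carrying \code{top_id}.
#' @param min_top threshold (default 10).
#' @return data.frame: id, chrom, pos, n_top_regions.
#' @export
detect_top_hotspots <- function(regions, min_top = 10L) {
  if (!nrow(regions))
    return(data.frame(id = character(0), chrom = character(0),
                      pos = numeric(0), n_top_regions = integer(0)))
  cnt <- table(regions$top_id)
  ids <- names(cnt)[cnt >= min_top]
  out <- do.call(rbind, lapply(ids, function(v) {
    r <- regions[regions$top_id == v, ][1, ]
    data.frame(id = v, chrom = r$chrom, pos = r$top_pos,
               n_top_regions = as.integer(cnt[[v]]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) return(detect_top_hotspots(regions[0, ], min_top))
  out
}

#' Overlap QTL intervals with eQTL regions
#'
#' Emits every (QTL, eQTL) pair whose extended eQTL interval intersects the
#' QTL interval on the same chromosome; intervals are closed, so sharing a
#' single bp counts as overlap.
#'
#' @param qtl data.frame: chrom, start, end, plus any id columns (e.g.
#'   trait).
#' @param regions data.frame with chrom, ext_start, ext_end (from
#'   \code{\link{call_regions}}).
#' @return data.frame pairing row indices and ids of overlapping intervals.
#' @export
overlap_intervals <- function(qtl, regions) {
  if (any(qtl$start > qtl$end) ||
      any(regions$ext_start > regions$ext_end))
    stop("malformed interval: start > end")
  out <- list()
  for (ch in intersect(unique(qtl$chrom), unique(regions$chrom))) {
    qi <- which(qtl$chrom == ch)
    ri <- which(regions$chrom == ch)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(qtl$start[qi], qtl$end[qi]),
      IRanges::IRanges(regions$ext_start[ri], regions$ext_end[ri]))
    if (!length(hits)) next
    out[[length(out) + 1]] <- data.frame(
      qtl_row = qi[S4Vectors::queryHits(hits)],
      region_row = ri[S4Vectors::subjectHits(hits)])
  }
  if (!length(out))
    return(data.frame(qtl_row = integer(0), region_row = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$qtl_row, res$region_row), , drop = FALSE]
  rownames(res) <- NULL
  res
}
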