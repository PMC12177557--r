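#' Read genotypes from a VCF
#'
#' Parses biallelic records into a dosage matrix: dosage = alt-allele count
#' from GT (unphased or phased), or rounded DS when \code{use_ds = TRUE}.
#' Multiallelic records are skipped and counted. Positions are 1-based as in
#' VCF.
#'
#' @param path VCF file (plain or bgzipped).
#' @param use_ds take dosages from the DS FORMAT field instead of GT.
#' @return a \code{\link{genotype_matrix}}; the number of skipped
#'   multiallelic records is attached as attribute
#'   \code{"n_multiallelic_skipped"}.
#' @export
read_genotypes <- function(path, use_ds = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (!nrow(fix)) stop("no records in VCF")
  multi <- grepl(",", fix$ALT)
  n_skip <- sum(multi)
  if (all(multi)) stop("no biallelic records in VCF")
  keep <- !multi
  if (use_ds) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    dos <- round(ds[keep, , drop = FALSE])
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
    a1 <- substr(gt, 1, 1)
    a2 <- substr(gt, 3, 3)
    dos <- matrix(suppressWarnings(as.numeric(a1) + as.numeric(a2)),
                  nrow = nrow(gt), dimnames = dimnames(gt))
  }
  fix <- fix[keep, , drop = FALSE]
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID)
  g <- genotype_matrix(t(dos), data.frame(
    id = ids, chrom = fix$CHROM, pos = as.numeric(fix$POS),
    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE))
  attr(g, "n_multiallelic_skipped") <- n_skip
  g
}

#' Write a genotype matrix as VCF
#'
#' Minimal VCF 4.2 with GT per sample (unphased; missing calls as "./.").
#'
#' @param geno a \code{\link{genotype_matrix}}.
#' @param path output file.
#' @export
write_genotypes_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  v <- geno$variants
  ref <- if ("ref" %in% names(v)) v$ref else "A"
  alt <- if ("alt" %in% names(v)) v$alt else "G"
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", geno$samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(v)), function(i) {
    d <- geno$dosage[, i]
    gt <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
    paste(c(v$chrom[i], v$pos[i], v$id[i], ref[i], alt[i], ".", "PASS",
            ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
}

#' Read a counts TSV (gene id column + one column per sample)
#' @param path TSV path; first column is the gene id.
#' @return genes x samples numeric matrix.
#' @export
read_counts <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  m
}

#' Write a matrix as TSV with an id column
#' @param m matrix with rownames.
#' @param path output path.
#' @param id_col name of the id column (default "id").
#' @export
write_matrix_tsv <- function(m, path, id_col = "id") {
  dt <- data.table::data.table(id = rownames(m))
  data.table::setnames(dt, "id", id_col)
  data.table::fwrite(cbind(dt, data.table::as.data.table(m)), path,
                     sep = "\t")
}

#' Read gene coordinates from BED (0-based half-open) into 1-based inclusive
#' @param path BED file with >= 4 columns (chrom, start, end, name).
#' @return data.frame: id, chrom, start, end (1-based inclusive).
#' @export
read_gene_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE)
  if (ncol(dt) < 4) stop("gene BED needs at least 4 columns")
  data.frame(id = dt[[4]], chrom = as.character(dt[[1]]),
             start = dt[[2]] + 1, end = dt[[3]],
             stringsAsFactors = FALSE)
}

#' Write gene coordinates as 6-column BED (0-based half-open)
#' @param genes data.frame: id, chrom, start, end (1-based inclusive).
#' @param path output path.
#' @export
write_gene_bed <- function(genes, path) {
  data.table::fwrite(data.table::data.table(
    chrom = genes$chrom, start = genes$start - 1, end = genes$end,
    name = genes$id, score = 0, strand = "+"),
    path, sep = "\t", col.names = FALSE)
}

#' Write a data.frame as TSV
#' @param df data.frame. @param path output path.
#' @export
write_tsv <- function(df, path) data.table::fwrite(df, path, sep = "\t")

#' Read a TSV into a data.frame
#' @param path input path.
#' @export
read_tsv <- function(path)
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
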