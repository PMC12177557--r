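sig_df <- function(pos, p, gene = "g1", chrom = "1") {
  data.frame(gene = gene, id = sprintf("v%04d", seq_along(pos)),
             chrom = chrom, pos = pos, p = p, stringsAsFactors = FALSE)
}

test_that("region calling groups, filters and extends as specified", {
  # clusters {1.0, 1.5} and {3.0} Mb, both under 3 SNPs: no regions
  r <- call_regions(sig_df(c(1e6, 1.5e6, 3e6), c(1e-8, 1e-8, 1e-8)))
  expect_equal(nrow(r), 0)
  # 1.0/1.4/1.9 Mb: one region, core 1.0-1.9, extended 0.5-2.4 Mb
  r2 <- call_regions(sig_df(c(1e6, 1.4e6, 1.9e6), c(1e-8, 1e-9, 1e-8)))
  expect_equal(nrow(r2), 1)
  expect_equal(c(r2$start, r2$end), c(1e6, 1.9e6))
  expect_equal(c(r2$ext_start, r2$ext_end), c(0.5e6, 2.4e6))
  expect_equal(r2$n_snps, 3L)
  expect_identical(r2$top_id, "v0002")
  # a gap of exactly 1 Mb splits ("less than 1 Mb apart" is strict)
  r3 <- call_regions(sig_df(c(1e6, 1.5e6, 2.5e6), rep(1e-8, 3)))
  expect_equal(nrow(r3), 0)   # splits into {2} and {1}
  r4 <- call_regions(sig_df(c(1e6, 1.5e6, 2.5e6 - 1), rep(1e-8, 3)))
  expect_equal(nrow(r4), 1)
  # extension floors at position 1
  r5 <- call_regions(sig_df(c(1e3, 2e3, 3e3), rep(1e-8, 3)))
  expect_equal(r5$ext_start, 1)
  expect_error(call_regions(rbind(sig_df(1e6, 1e-8, "g1"),
                                  sig_df(2e6, 1e-8, "g2"))), "single gene")
})

test_that("random region instances match the brute-force gap scan", {
  set.seed(123)
  for (i in 1:120) {
    k <- sample(3:40, 1)
    pos <- sort(sample.int(2e7, k))
    p <- 10^runif(k, -12, -7)
    r <- call_regions(sig_df(pos, p))
    o <- oracle_regions(pos, p)
    if (is.null(o)) {
      expect_equal(nrow(r), 0)
    } else {
      expect_equal(nrow(r), nrow(o))
      expect_equal(r$start, o$start)
      expect_equal(r$end, o$end)
      expect_equal(r$ext_start, o$ext_start)
      expect_equal(r$ext_end, o$ext_end)
      expect_equal(r$n_snps, o$n_snps)
      expect_equal(r$top_pos, o$top_pos)
    }
  }
})

test_that("region count is monotone in min_snps and gap", {
  set.seed(7)
  pos <- sort(sample.int(3e7, 60))
  p <- rep(1e-8, 60)
  n3 <- nrow(call_regions(sig_df(pos, p), min_snps = 3))
  n5 <- nrow(call_regions(sig_df(pos, p), min_snps = 5))
  expect_lte(n5, n3)
  nwide <- nrow(call_regions(sig_df(pos, p), gap = 2e6, min_snps = 3))
  # a larger gap merges clusters: never more regions of >= 3 SNPs lost
  expect_gte(sum(call_regions(sig_df(pos, p), gap = 2e6)$n_snps),
             sum(call_regions(sig_df(pos, p))$n_snps))
})

test_that("cis/trans classification uses an inclusive 1 Mb boundary", {
  expect_identical(classify_cis_trans("1", 5e5, "1", 1e6, 1.2e6), "cis")
  expect_identical(classify_cis_trans("2", 1e6, "1", 1e6, 1.2e6), "trans")
  # exactly 1 Mb away is cis (inclusive)
  expect_identical(classify_cis_trans("1", 2.2e6 + 1e6, "1", 1e6, 2.2e6),
                   "cis")
  expect_identical(classify_cis_trans("1", 2.2e6 + 1e6 + 1, "1", 1e6, 2.2e6),
                   "trans")
  # inside the gene: distance 0
  expect_identical(classify_cis_trans("1", 1.1e6, "1", 1e6, 1.2e6), "cis")
})

test_that("hotspots require >= 10 distinct genes; planted hotspot recovered", {
  mk <- function(ngenes) {
    data.frame(gene = sprintf("g%02d", seq_len(ngenes)),
               id = rep("hot", ngenes), chrom = rep("1", ngenes),
               pos = rep(5e6, ngenes))
  }
  expect_equal(nrow(detect_hotspots(mk(10))), 1)
  expect_equal(nrow(detect_hotspots(mk(9))), 0)
  expect_equal(nrow(detect_hotspots(mk(0))), 0)
  # duplicated (variant, gene) rows are not double-counted
  dup <- rbind(mk(9), mk(9)[1, ])
  expect_equal(nrow(detect_hotspots(dup)), 0)
  # hotspot set at min_genes = k+1 is nested in the set at k
  set.seed(31)
  rec <- data.frame(gene = sprintf("g%02d", sample(30, 500, TRUE)),
                    id = sprintf("v%02d", sample(15, 500, TRUE)),
                    chrom = "1", pos = 1e6)
  for (k in c(5, 8, 12)) {
    hk <- detect_hotspots(rec, min_genes = k)$id
    hk1 <- detect_hotspots(rec, min_genes = k + 1)$id
    expect_true(all(hk1 %in% hk))
  }
})

test_that("top-hotspots count regions topped by the same variant", {
  mk_regions <- function(top_ids) {
    data.frame(gene = sprintf("g%02d", seq_along(top_ids)), chrom = "1",
               start = 1e6, end = 2e6, ext_start = 5e5, ext_end = 2.5e6,
               n_snps = 3L, top_id = top_ids,
               top_pos = 1.5e6, top_p = 1e-9, stringsAsFactors = FALSE)
  }
  th <- detect_top_hotspots(mk_regions(rep("vA", 10)))
  expect_equal(nrow(th), 1)
  expect_equal(th$n_top_regions, 10L)
  expect_equal(nrow(detect_top_hotspots(mk_regions(sprintf("v%02d", 1:12)))),
               0)
  # p ties inside a region resolve to the smallest position before counting
  rec <- sig_df(c(1e6, 1.1e6, 1.2e6), rep(1e-9, 3))
  r <- call_regions(rec)
  expect_identical(r$top_id, "v0001")
})

test_that("interval overlap matches the quadratic brute force", {
  q1 <- data.frame(chrom = "1", start = 10e6, end = 20e6, trait = "t1")
  r1 <- data.frame(chrom = "1", ext_start = 15e6, ext_end = 25e6)
  expect_equal(nrow(overlap_intervals(q1, r1)), 1)
  r2 <- data.frame(chrom = "2", ext_start = 15e6, ext_end = 25e6)
  expect_equal(nrow(overlap_intervals(q1, r2)), 0)
  # a single shared bp counts (closed intervals)
  r3 <- data.frame(chrom = "1", ext_start = 20e6, ext_end = 25e6)
  expect_equal(nrow(overlap_intervals(q1, r3)), 1)
  expect_error(overlap_intervals(data.frame(chrom = "1", start = 5, end = 1),
                                 r1), "malformed")
  set.seed(77)
  for (i in 1:100) {
    nq <- sample(2:12, 1); nr <- sample(2:12, 1)
    qs <- sample.int(1e7, nq)
    rs <- sample.int(1e7, nr)
    qtl <- data.frame(chrom = sample(c("1", "2"), nq, TRUE),
                      start = qs, end = qs + sample.int(2e6, nq))
    reg <- data.frame(chrom = sample(c("1", "2"), nr, TRUE),
                      ext_start = rs, ext_end = rs + sample.int(2e6, nr))
    got <- overlap_intervals(qtl, reg)
    want <- oracle_overlap(qtl, reg)
    want <- want[order(want$qtl_row, want$region_row), , drop = FALSE]
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("region labels are cis when any member SNP is within the window", {
  genes <- data.frame(id = "g1", chrom = "1", start = 10e6, end = 10.1e6)
  reg_near <- call_regions(sig_df(c(8.5e6, 8.7e6, 9.2e6), rep(1e-9, 3)))
  reg_far <- call_regions(sig_df(c(20e6, 20.2e6, 20.4e6), rep(1e-9, 3)))
  expect_identical(label_regions(reg_near, genes)$label, "cis")
  expect_identical(label_regions(reg_far, genes)$label, "trans")
})
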