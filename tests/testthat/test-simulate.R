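test_that("two-founder mosaic forces perfect LD inside a shared block", {
  # founders differ at two adjacent SNPs; with only 2 founders every
  # segregating pair is perfectly correlated at the founder level, so a pair
  # falling in one copied block has r^2 = 1
  cfg <- sim_config(n_samples = 200, n_variants = 40, chrom_length = 1e6,
                    n_founder_haplotypes = 2, block_length_mean = 1e6,
                    founder_ld_length = 1e9, miss_rate = 0, seed = 11)
  g <- simulate_genotypes(cfg)
  pos <- g$variants$pos
  adj <- which(diff(pos) < 5e3)
  expect_gt(length(adj), 0)
  r2 <- vapply(adj, function(i)
    ld_r2(g$dosage[, i], g$dosage[, i + 1]), numeric(1))
  expect_true(any(abs(r2 - 1) < 1e-12))
})

test_that("genotype simulation is deterministic in the seed", {
  cfg1 <- sim_config(n_samples = 40, n_variants = 60, chrom_length = 2e6,
                     seed = 5)
  g1 <- simulate_genotypes(cfg1)
  g2 <- simulate_genotypes(cfg1)
  g3 <- simulate_genotypes(sim_config(n_samples = 40, n_variants = 60,
                                      chrom_length = 2e6, seed = 6))
  expect_identical(g1$dosage, g2$dosage)
  expect_identical(g1$variants, g2$variants)
  expect_false(identical(g1$dosage, g3$dosage))
})

test_that("emitted MAF respects the floor and LD decays with distance", {
  cfg <- sim_config(n_samples = 500, n_variants = 400, chrom_length = 2e7,
                    maf_min = 0.05, seed = 21)
  g <- simulate_genotypes(cfg)
  expect_true(all(g$variants$maf >= 0.05))
  # pairs more than 5 mean block lengths apart are essentially unlinked
  pos <- g$variants$pos
  far_gap <- 5 * cfg$block_length_mean
  set.seed(1)
  pairs <- which(outer(pos, pos, function(a, b) b - a) > far_gap,
                 arr.ind = TRUE)
  pairs <- pairs[sample.int(nrow(pairs), 400), , drop = FALSE]
  r2 <- vapply(seq_len(nrow(pairs)), function(k)
    ld_r2(g$dosage[, pairs[k, 1]], g$dosage[, pairs[k, 2]]), numeric(1))
  expect_lt(mean(r2), 0.05)
})

test_that("fewer than two founders is an error", {
  expect_error(sim_config(n_founder_haplotypes = 1), "polymorphism")
})

test_that("expression truth table closes over the emitted panel", {
  cfg <- sim_config(n_samples = 60, n_variants = 300, chrom_length = 1e7,
                    n_genes = 40, cis_fraction = 0.5,
                    hotspot_spec = list(list(variant = 50, n_targets = 12,
                                             beta = 0.6)),
                    seed = 31)
  g <- simulate_genotypes(cfg)
  ex <- simulate_expression(g, cfg)
  expect_true(all(ex$truth$cis$variant %in% g$variants$id))
  expect_true(all(ex$truth$cis$gene %in% ex$genes$id))
  expect_true(all(ex$truth$hotspots$variant %in% g$variants$id))
  tg <- strsplit(ex$truth$hotspots$targets, ",")[[1]]
  expect_length(tg, 12)
  expect_true(all(tg %in% ex$genes$id))
  # planted cis variants sit within 1 Mb of their gene TSS
  vi <- match(ex$truth$cis$variant, g$variants$id)
  gi <- match(ex$truth$cis$gene, ex$genes$id)
  expect_true(all(abs(g$variants$pos[vi] - ex$genes$tss[gi]) <= 1e6))
  expect_identical(dim(ex$counts), c(40L, 60L))
  expect_true(all(ex$counts >= 0))
})

test_that("a hotspot spec pointing outside the panel is an error", {
  cfg <- sim_config(n_samples = 30, n_variants = 50, chrom_length = 1e6,
                    n_genes = 15,
                    hotspot_spec = list(list(variant = 10000, n_targets = 10,
                                             beta = 1)),
                    seed = 2)
  g <- simulate_genotypes(cfg)
  expect_error(simulate_expression(g, cfg), "outside")
})

test_that("simulated traits are standardized and deterministic", {
  g <- small_panel(n = 100, m = 80, seed = 3)
  y1 <- simulate_trait(g, shared_variant = 10, effect = 0.5, h2 = 0.3,
                       seed = 4)
  y2 <- simulate_trait(g, shared_variant = 10, effect = 0.5, h2 = 0.3,
                       seed = 4)
  expect_identical(y1, y2)
  expect_equal(mean(y1), 0, tolerance = 1e-12)
  expect_equal(stats::var(y1), 1, tolerance = 1e-12)
  expect_error(simulate_trait(g, 10, 0.5, h2 = 1.2, seed = 1), "h2")
  expect_error(simulate_trait(g, "nosuch", 0.5, h2 = 0, seed = 1),
               "not found")
})

test_that("null traits give approximately uniform scan p-values", {
  g <- small_panel(n = 150, m = 200, seed = 13, miss_rate = 0)
  y <- simulate_trait(g, shared_variant = NULL, effect = 0, h2 = 0, seed = 8)
  fit <- fit_null(y, NULL, diag(length(y)))
  sc <- scan_snps(fit, g)
  ks <- suppressWarnings(stats::ks.test(sc$p, "punif"))
  expect_gt(ks$p.value, 1e-3)
})

test_that("founder allele frequencies are recovered in large samples", {
  cfg <- sim_config(n_samples = 600, n_variants = 80, chrom_length = 4e6,
                    maf_min = 0.01, miss_rate = 0, seed = 17)
  g <- simulate_genotypes(cfg)
  H <- attr(g, "founders")
  fr_founder <- colMeans(H)
  seg <- fr_founder > 0 & fr_founder < 1
  p_sample <- colMeans(g$dosage) / 2
  # each of the 2n haplotype alleles is an independent draw from the founder
  # panel, so the sample frequency is binomial around the founder frequency
  sd_bin <- sqrt(fr_founder * (1 - fr_founder) / (2 * cfg$n_samples))
  frac_in <- mean(abs(p_sample[seg] - fr_founder[seg]) <= 3 * sd_bin[seg])
  expect_gt(frac_in, 0.9)
})
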