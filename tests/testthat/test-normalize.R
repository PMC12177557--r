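test_that("TMM factors are unity on identical or purely depth-scaled libraries", {
  set.seed(1)
  base <- rnbinom(300, mu = 100, size = 5) + 1
  m <- cbind(a = base, b = base, c = base)
  expect_equal(unname(tmm_factors(m)), rep(1, 3), tolerance = 1e-12)
  # doubling depth changes no composition: after factor correction the cpm
  # profiles coincide
  m2 <- cbind(a = base, b = 2 * base)
  f <- tmm_factors(m2)
  lc <- log_cpm(m2, f)
  expect_equal(lc[, 1], lc[, 2], tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("TMM factors match an independent trimmed weighted-mean evaluation", {
  set.seed(42)
  for (rep in 1:3) {
    m <- matrix(rnbinom(200 * 6, mu = exp(runif(200, 2, 7)), size = 3),
                nrow = 200, ncol = 6,
                dimnames = list(NULL, paste0("s", 1:6)))
    m <- m[rowSums(m) > 0, ]
    expect_equal(unname(tmm_factors(m)), unname(oracle_tmm(m)),
                 tolerance = 1e-10)
  }
})

test_that("an all-zero sample is rejected by name", {
  m <- cbind(good = c(5, 3, 2), bad = c(0, 0, 0))
  expect_error(tmm_factors(m), "bad")
})

test_that("log-cpm masks zeros, maps unit cpm to 0, and matches hand arithmetic", {
  counts <- matrix(c(0, 10, 90,
                     4, 16, 80,
                     1, 9, 90), nrow = 3,
                   dimnames = list(c("g1", "g2", "g3"), c("s1", "s2", "s3")))
  f <- c(1, 1, 1)
  lc <- log_cpm(counts, f)
  expect_true(is.na(lc["g1", "s1"]))               # zero -> missing, not -Inf
  lib <- colSums(counts)
  # hand-computed: log2(count / libsize * 1e6)
  expect_equal(lc["g2", "s1"], log2(10 / lib[1] * 1e6), ignore_attr = TRUE)
  expect_equal(lc["g3", "s2"], log2(80 / lib[2] * 1e6), ignore_attr = TRUE)
  # a count equal to libsize * factor / 1e6 has cpm 1, log2 value 0
  n <- 1e6
  counts2 <- matrix(c(1, n - 1, 1, n - 1), 2,
                    dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(log_cpm(counts2, c(1, 1))["g1", "s1"], 0, ignore_attr = TRUE)
  expect_error(log_cpm(matrix(-1), 1), "non-negative")
})

test_that("the cpm filter applies the strict >35% rule at the boundary", {
  # 5 genes passing the threshold in 0, 20, 35, 36 and 100 percent of 100
  # samples: only the 36% and 100% genes survive
  n <- 100
  lo <- -5; hi <- 5                     # log2 cpm below / above any t in use
  mk <- function(k) c(rep(hi, k), rep(lo, n - k))
  m <- rbind(g0 = mk(0), g20 = mk(20), g35 = mk(35), g36 = mk(36),
             g100 = mk(100))
  res <- filter_genes(m, min_lib_millions = 14.5)
  expect_identical(res$retained, c("g36", "g100"))
  expect_equal(res$report$pass_frac,
               c(0, 0.2, 0.35, 0.36, 1))
  # threshold resolves to cpm > 0.69 for a 14.5M minimum library
  expect_equal(10 / 14.5, 0.69, tolerance = 0.001)
  expect_error(filter_genes(m[0, , drop = FALSE], 14.5), "empty")
})

test_that("raising the cpm threshold never grows the retained set", {
  set.seed(7)
  m <- matrix(rnorm(50 * 40, mean = 0, sd = 3), 50, 40,
              dimnames = list(sprintf("g%02d", 1:50), NULL))
  prev <- NULL
  for (lmin in c(40, 20, 10, 5, 2)) {  # decreasing L_min => increasing t
    ret <- filter_genes(m, lmin)$retained
    if (!is.null(prev)) expect_true(all(ret %in% prev))
    prev <- ret
  }
})

test_that("leave-one-out Shapiro-Wilk removes a gross outlier and is idempotent", {
  set.seed(5)
  x <- rnorm(49)
  xo <- c(x, 10)
  names(xo) <- sprintf("s%02d", 1:50)
  r <- remove_outliers(xo)
  expect_identical(r$removed, "s50")
  expect_true(is.na(r$values["s50"]))
  # an already-normal vector is untouched, twice
  xn <- rnorm(50); names(xn) <- sprintf("s%02d", 1:50)
  r1 <- remove_outliers(xn)
  r2 <- remove_outliers(r1$values)
  expect_identical(r1$values, xn)
  expect_identical(r2$values, xn)
  expect_error(remove_outliers(rnorm(5)), "at least 8")
})

test_that("outlier removal is capped and its false-removal rate tracks alpha", {
  set.seed(99)
  # heavy contamination: never more than max_removals samples masked
  x <- c(rnorm(40), 8, 9, 10, 11, 12)
  r <- remove_outliers(x, max_removals = 3)
  expect_lte(length(r$removed), 3)
  # clean normal vectors: removal happens at roughly the alpha rate
  removed <- vapply(1:300, function(i) {
    length(remove_outliers(rnorm(50), alpha_sw = 0.01)$removed) > 0
  }, logical(1))
  expect_lt(mean(removed), 0.06)
})

test_that("scaling one sample's counts leaves its normalized profile invariant", {
  set.seed(11)
  base <- rnbinom(400, mu = 200, size = 10) + 1
  m <- cbind(s1 = base, s2 = base, s3 = base, s4 = 3 * base)
  f <- tmm_factors(m)
  # a pure depth change is absorbed by the library size: the TMM factor
  # stays at 1 and the effective library size scales by c
  expect_equal(f[["s4"]], f[["s1"]], tolerance = 1e-6)
  lc <- log_cpm(m, f)
  eff <- attr(lc, "eff_libsize")
  expect_equal(unname(eff[["s4"]] / eff[["s1"]]), 3, tolerance = 1e-6)
  expect_equal(lc[, "s4"], lc[, "s1"], tolerance = 1e-6, ignore_attr = TRUE)
})
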