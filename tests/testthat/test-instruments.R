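# Instrument selection: p-value thresholding, LD clumping, F filtering.

test_that("p-value selection applies the primary threshold when enough SNPs pass", {
  z <- c(6, 6.5, 7, 3, 2, 1, 4, 4.2, 2.5, 0.5)  # 3 SNPs beyond 5.45 sigma
  t <- make_sumstats(beta = z * 0.01, se = rep(0.01, 10))
  sel <- select_by_pvalue(t, 5e-8, 1e-5, min_snps = 3)
  expect_equal(nrow(sel$snps), 3)
  expect_false(sel$fallback_used)
  expect_equal(sel$p_threshold_used, 5e-8)
})

test_that("too few genome-wide hits triggers the fallback threshold", {
  z <- c(4.5, 4.6, 4.7, 4.8, 2, 1)  # 0 pass 5e-8; 4 pass 1e-5 (|z|>4.42)
  t <- make_sumstats(beta = z * 0.01, se = rep(0.01, 6))
  sel <- select_by_pvalue(t, 5e-8, 1e-5, min_snps = 3)
  expect_equal(nrow(sel$snps), 4)
  expect_true(sel$fallback_used)
  expect_equal(sel$p_threshold_used, 1e-5)
})

test_that("zero hits under both thresholds is a flagged empty selection, not an error", {
  t <- make_sumstats(beta = c(0.01, 0.02), se = c(0.01, 0.02))
  sel <- select_by_pvalue(t, 5e-8, 1e-5)
  expect_equal(nrow(sel$snps), 0)
  expect_true(sel$no_instruments)
})

test_that("fallback is never flagged when enough SNPs pass the primary threshold", {
  for (seed in 1:5) {
    set.seed(seed)
    z <- rnorm(20, 0, 4)
    t <- make_sumstats(beta = z * 0.01, se = rep(0.01, 20))
    thr <- 1e-3
    k <- sum(t$P < thr)
    sel <- select_by_pvalue(t, thr, thr, min_snps = max(1, k))
    expect_false(sel$fallback_used)
  }
})

test_that("clumping keeps the more significant SNP of a correlated pair", {
  d <- make_sumstats(snp = c("rs1", "rs2"), beta = c(0.07, 0.065),
                     se = 0.01, pos = c(1e6, 1.1e6))
  ld_hi <- make_ld(c("rs1", "rs2"),
                   data.frame(a = "rs1", b = "rs2", r2 = 0.5))
  cl <- ld_clump(d, ld_hi, r2_max = 0.01, window_kb = 10000)
  expect_equal(cl$kept$SNP, "rs1")
  expect_equal(unname(cl$dropped["rs2"]), "clumped")

  ld_lo <- make_ld(c("rs1", "rs2"),
                   data.frame(a = "rs1", b = "rs2", r2 = 0.005))
  expect_equal(nrow(ld_clump(d, ld_lo, 0.01, 10000)$kept), 2)
})

test_that("SNPs outside the window or on other chromosomes never exclude each other", {
  d <- make_sumstats(snp = c("rs1", "rs2", "rs3"),
                     beta = c(0.07, 0.065, 0.06), se = 0.01,
                     chr = c("1", "1", "2"), pos = c(1e6, 1e6 + 2e7, 1e6))
  ld <- make_ld(c("rs1", "rs2", "rs3"),
                data.frame(a = c("rs1", "rs1"), b = c("rs2", "rs3"),
                           r2 = c(0.9, 0.9)))
  cl <- ld_clump(d, ld, 0.01, window_kb = 10000)
  # rs2 is 20 Mb away (window 10 Mb), rs3 is on another chromosome
  expect_setequal(cl$kept$SNP, c("rs1", "rs2", "rs3"))
})

test_that("greedy clumping matches a brute-force oracle on random candidate sets", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 6
    ids <- paste0("rs", 1:n)
    r2 <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      r2[i, j] <- r2[j, i] <- sample(c(0, 0.005, 0.02, 0.5), 1)
    diag(r2) <- 1
    d <- make_sumstats(snp = ids, beta = rnorm(n, 0, 0.07),
                       se = rep(0.01, n), chr = "1",
                       pos = sort(sample(1:20, n)) * 1e6)
    ld <- ld_matrix(r2)
    got <- ld_clump(d, ld, 0.01, 10000)$kept$SNP
    expect_equal(got, oracle_clump(as.data.frame(d), r2, 0.01, 10000))
  }
})

test_that("clumped output is an independent set and input-order invariant", {
  set.seed(99)
  n <- 12
  ids <- paste0("rs", 1:n)
  r2 <- matrix(runif(n * n, 0, 0.6), n, n, dimnames = list(ids, ids))
  r2 <- (r2 + t(r2)) / 2
  diag(r2) <- 1
  d <- make_sumstats(snp = ids, beta = rnorm(n, 0, 0.07), se = rep(0.01, n),
                     chr = "1", pos = (1:n) * 1e5)
  ld <- ld_matrix(r2)
  kept <- ld_clump(d, ld, r2_max = 0.1, window_kb = 10000)$kept$SNP
  for (a in kept) for (b in kept) if (a != b)
    expect_lt(r2[a, b], 0.1)
  shuf <- d[sample(n), ]
  expect_equal(sort(ld_clump(shuf, ld, 0.1, 10000)$kept$SNP), sort(kept))
})

test_that("candidates missing from the LD matrix are dropped with a reason", {
  d <- make_sumstats(snp = c("rs1", "rsX"), beta = c(0.07, 0.08), se = 0.01)
  ld <- make_ld("rs1")
  cl <- ld_clump(d, ld, 0.01, 10000)
  expect_equal(cl$kept$SNP, "rs1")
  expect_equal(unname(cl$dropped["rsX"]), "no_ld_info")
})

test_that("F statistics follow (beta/se)^2 with the documented R2 variant", {
  expect_equal(f_statistic(0.1, 0.02), 25)
  expect_equal(f_statistic(0.03, 0.01), 9)
  expect_equal(f_statistic(0, 0.01), 0)
  expect_error(f_statistic(0.1, 0), "positive")
  # R2 form: R2 = 2*eaf*(1-eaf)*beta^2, F = (n-2) R2/(1-R2)
  r2 <- 2 * 0.3 * 0.7 * 0.1^2
  expect_equal(f_statistic(0.1, 0.02, method = "r2", n = 1000, eaf = 0.3),
               998 * r2 / (1 - r2))
})

test_that("weak instruments are filtered with reasons and F recorded for all", {
  t <- make_sumstats(snp = c("a", "b", "c"), beta = c(0.05, 0.03, 0.1),
                     se = c(0.01, 0.01, 0.01))  # F = 25, 9, 100
  fw <- filter_weak(t, f_min = 10)
  expect_equal(fw$kept$SNP, c("a", "c"))
  expect_equal(unname(fw$dropped["b"]), "weak_instrument")
  expect_equal(unname(fw$f_statistics), c(25, 9, 100))
  expect_equal(nrow(filter_weak(t, f_min = 0)$kept), 3)
  all_weak <- filter_weak(t, f_min = 1000)
  expect_equal(nrow(all_weak$kept), 0)
  expect_equal(length(all_weak$dropped), 3)
})

test_that("the selection ladder partitions candidates into kept and dropped", {
  set.seed(5)
  tri <- simulate_triplet(scenario_config(n_snps = 100, n_causal_exp = 30,
                                          n_causal_med = 0, seed = 17))
  sel <- select_instruments(tri$exposure, tri$ld, screen_config())
  expect_equal(nrow(sel$kept) + length(sel$dropped), nrow(tri$exposure))
  expect_length(intersect(sel$kept$SNP, names(sel$dropped)), 0)
  expect_true(all(sel$kept$P < sel$p_threshold_used))
  expect_true(all(sel$f_statistics[sel$kept$SNP] >= 10))
})

test_that("LD matrices round-trip through the tab-delimited format", {
  ids <- c("rs1", "rs2", "rs3")
  ld <- make_ld(ids, data.frame(a = "rs1", b = "rs3", r2 = 0.4))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ld_matrix(ld, path)
  ld2 <- read_ld_matrix(path)
  expect_equal(ld2$r2, ld$r2, tolerance = 1e-12)
})
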