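# The causal estimators: Wald, IVW, Egger, weighted median, modes, MVMR.

test_that("Wald ratio matches the delta-method formulas", {
  h <- make_h(0.5, 0.05, 0.1, 0.02)
  w <- wald_ratio(h)
  expect_equal(w$beta, 0.2)
  expect_equal(w$se, 0.04)
  w2 <- wald_ratio(h, se_order = "second")
  expect_equal(w2$se, sqrt(0.0016 + 0.0004), tolerance = 1e-12)
  # unit exposure effect: ratio is the outcome effect
  expect_equal(wald_ratio(make_h(1, 0.05, 0.123, 0.02))$beta, 0.123)
  expect_error(wald_ratio(make_h(0, 0.05, 0.1, 0.02)), "nonzero")
})

test_that("IVW with one instrument reduces to the Wald ratio", {
  h <- make_h(0.5, 0.05, 0.1, 0.02)
  expect_message(iv <- ivw(h), "single instrument")
  w <- wald_ratio(h)
  expect_equal(iv$beta, w$beta)
  expect_equal(iv$se, w$se)
  expect_equal(iv$method, "ivw_fixed")
})

test_that("IVW equals the closed-form weighted least squares through the origin", {
  # equal beta_exp, equal se_out: equal weights, ratios 0.2 and 0.4
  h <- make_h(c(0.5, 0.5), c(0.05, 0.05), c(0.1, 0.2), c(0.02, 0.02))
  expect_equal(ivw(h, re_mode = "fixed")$beta, 0.3)
  # general closed form on unequal weights
  set.seed(2)
  h2 <- make_h(rnorm(8, 0.1, 0.02), runif(8, 0.005, 0.02),
               rnorm(8, 0.05, 0.02), runif(8, 0.005, 0.03))
  w <- 1 / h2$se_out^2
  expect_equal(ivw(h2, re_mode = "fixed")$beta,
               sum(w * h2$beta_exp * h2$beta_out) / sum(w * h2$beta_exp^2),
               tolerance = 1e-12)
  expect_equal(ivw(h2, re_mode = "fixed")$se,
               1 / sqrt(sum(h2$beta_exp^2 / h2$se_out^2)), tolerance = 1e-12)
})

test_that("multiplicative random effects never shrinks the fixed-effect SE", {
  set.seed(3)
  for (rep in 1:10) {
    h <- make_h(rnorm(10, 0.1, 0.03), runif(10, 0.005, 0.02),
                rnorm(10, 0.03, 0.03), runif(10, 0.005, 0.02))
    fx <- ivw(h, re_mode = "fixed")
    re <- ivw(h, re_mode = "multiplicative_random")
    expect_equal(re$beta, fx$beta)
    expect_gte(re$se, fx$se)
  }
})

test_that("MR-Egger recovers exact linear and affine instrument structures", {
  g <- c(0.08, 0.12, 0.2, 0.15, 0.1)
  # exact proportionality: slope 0.5, intercept 0
  h <- make_h(g, rep(0.01, 5), 0.5 * g, rep(0.02, 5))
  eg <- suppressWarnings(mr_egger(h))
  expect_equal(eg$slope$beta, 0.5, tolerance = 1e-10)
  expect_equal(eg$intercept$beta, 0, tolerance = 1e-10)
  # exact affine structure: directional pleiotropy 0.05
  h2 <- make_h(g, rep(0.01, 5), 0.05 + 0.5 * g, rep(0.02, 5))
  eg2 <- suppressWarnings(mr_egger(h2))
  expect_equal(eg2$slope$beta, 0.5, tolerance = 1e-10)
  expect_equal(eg2$intercept$beta, 0.05, tolerance = 1e-10)
  expect_error(mr_egger(make_h(g[1:2], rep(0.01, 2), g[1:2], rep(0.01, 2))),
               "3")
})

test_that("weighted median interpolates the weighted CDF at one half", {
  # equal weights, odd count: the plain median
  h <- make_h(rep(1, 3), rep(0.01, 3), c(0.1, 0.2, 0.9), rep(0.02, 3))
  expect_equal(weighted_median(h, n_boot = 50, seed = 1)$beta, 0.2)
  # one SNP carrying almost all weight dominates
  h2 <- make_h(rep(1, 4), rep(0.01, 4), c(0.1, 0.5, 0.52, 0.9),
               c(0.0005, 0.7, 0.8, 0.9))
  expect_equal(weighted_median(h2, n_boot = 50, seed = 1)$beta, 0.1,
               tolerance = 1e-3)
})

test_that("weighted median matches the CDF-interpolation oracle on hand-set weights", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 4
    gx <- runif(n, 0.05, 0.2)
    h <- make_h(gx, runif(n, 0.005, 0.02), rnorm(n, 0.3, 0.1) * gx,
                runif(n, 0.01, 0.1))
    got <- weighted_median(h, n_boot = 10, seed = 1)$beta
    want <- oracle_weighted_median(h$beta_out / h$beta_exp,
                                   h$beta_exp^2 / h$se_out^2)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("mode estimators find the dominant ratio cluster", {
  # degenerate: identical ratios for any phi
  g <- runif(5, 0.05, 0.2)
  h <- make_h(g, rep(0.01, 5), 0.3 * g, rep(0.02, 5))
  for (phi in c(0.5, 1, 2))
    expect_equal(mode_estimate(h, "simple", phi, n_boot = 20, seed = 1)$beta,
                 0.3, tolerance = 1e-9)
  # 7 SNPs at ratio 0.2, 3 at 0.8: the larger cluster wins
  r <- c(rep(0.2, 7), rep(0.8, 3)) + seq(-0.01, 0.01, length.out = 10)
  h2 <- make_h(rep(1, 10), rep(0.01, 10), r, rep(0.02, 10))
  m <- mode_estimate(h2, "simple", phi = 1, n_boot = 20, seed = 1)
  expect_equal(m$beta, 0.2, tolerance = 0.05)
  expect_equal(m$beta, oracle_mode(r, rep(1, 10), 1), tolerance = 1e-10)
  # weighted variant against the oracle with inverse-variance weights
  h3 <- make_h(rep(1, 10), rep(0.01, 10), r, runif(10, 0.01, 0.05))
  m3 <- mode_estimate(h3, "weighted", phi = 1, n_boot = 20, seed = 1)
  expect_equal(m3$beta, oracle_mode(r, 1 / h3$se_out^2, 1), tolerance = 1e-10)
})

test_that("doubling phi doubles the kernel bandwidth", {
  set.seed(8)
  g <- runif(6, 0.05, 0.2)
  h <- make_h(g, rep(0.01, 6), rnorm(6, 0.3, 0.05) * g, rep(0.02, 6))
  b1 <- attr(mode_estimate(h, "simple", phi = 1, n_boot = 10, seed = 1),
             "bandwidth")
  b2 <- attr(mode_estimate(h, "simple", phi = 2, n_boot = 10, seed = 1),
             "bandwidth")
  expect_equal(b2, 2 * b1)
})

test_that("bootstrap SEs are reproducible under a fixed seed", {
  set.seed(10)
  g <- runif(6, 0.05, 0.2)
  h <- make_h(g, rep(0.01, 6), rnorm(6, 0.3, 0.05) * g, rep(0.02, 6))
  a <- weighted_median(h, n_boot = 200, seed = 42)
  b <- weighted_median(h, n_boot = 200, seed = 42)
  expect_identical(a$se, b$se)
  c1 <- mode_estimate(h, "weighted", n_boot = 200, seed = 42)
  c2 <- mode_estimate(h, "weighted", n_boot = 200, seed = 42)
  expect_identical(c1$se, c2$se)
})

test_that("multivariable IVW solves exact linear systems", {
  g <- c(0.1, 0.2, 0.15, 0.08, 0.12)
  m <- c(0.05, -0.02, 0.1, 0.07, -0.04)
  y <- 0.4 * g + 0.1 * m
  est <- mvmr_ivw(cbind(x = g, m = m), y, rep(0.02, 5))
  expect_equal(est$beta[est$exposure == "x"], 0.4, tolerance = 1e-10)
  expect_equal(est$beta[est$exposure == "m"], 0.1, tolerance = 1e-10)
})

test_that("with an orthogonal null mediator the exposure coefficient equals univariable IVW", {
  g <- c(1, 1, 1, 1)
  m <- c(1, -1, 1, -1)  # orthogonal to g under equal weights
  y <- c(0.35, 0.42, 0.4, 0.43)
  se <- rep(0.02, 4)
  est <- mvmr_ivw(cbind(exposure = g, mediator = m), y, se)
  uni <- ivw(make_h(g, rep(0.01, 4), y, se), re_mode = "fixed")
  expect_equal(est$beta[est$exposure == "exposure"], uni$beta,
               tolerance = 1e-10)
})

test_that("MVMR rejects rank-deficient and collinear designs", {
  g <- c(0.1, 0.2, 0.15)
  expect_error(mvmr_ivw(cbind(g, g * 2, g + 1), 0.4 * g, rep(0.02, 3)),
               "more SNPs")
  expect_error(mvmr_ivw(cbind(a = g, b = 2 * g), 0.4 * g + rnorm(3, 0, 1e-12),
                        rep(0.02, 3)), "collinear")
})

test_that("estimators are equivariant under exposure-allele reorientation", {
  set.seed(21)
  n <- 8
  g <- rnorm(n, 0.1, 0.05)
  h <- make_h(g, runif(n, 0.005, 0.02), 0.3 * g + rnorm(n, 0, 0.02),
              runif(n, 0.01, 0.03))
  flip <- c(1, 4, 7)
  h2 <- h
  h2$beta_exp[flip] <- -h2$beta_exp[flip]
  h2$beta_out[flip] <- -h2$beta_out[flip]
  expect_equal(ivw(h2)$beta, ivw(h)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(h2)$slope$beta, mr_egger(h)$slope$beta,
               tolerance = 1e-12)
  expect_equal(mr_egger(h2)$intercept$beta, mr_egger(h)$intercept$beta,
               tolerance = 1e-12)
  expect_equal(weighted_median(h2, n_boot = 10, seed = 1)$beta,
               weighted_median(h, n_boot = 10, seed = 1)$beta,
               tolerance = 1e-12)
  expect_equal(mode_estimate(h2, "weighted", n_boot = 10, seed = 1)$beta,
               mode_estimate(h, "weighted", n_boot = 10, seed = 1)$beta,
               tolerance = 1e-12)
})

test_that("homogeneous low-noise instruments drive all estimators to one value", {
  set.seed(33)
  n <- 15
  g <- runif(n, 0.08, 0.2)
  h <- make_h(g, rep(1e-5, n), 0.45 * g + rnorm(n, 0, 1e-6), rep(1e-4, n))
  ests <- c(ivw(h)$beta, mr_egger(h)$slope$beta,
            weighted_median(h, n_boot = 10, seed = 1)$beta,
            mode_estimate(h, "simple", n_boot = 10, seed = 1)$beta,
            mode_estimate(h, "weighted", n_boot = 10, seed = 1)$beta)
  expect_lt(max(ests) - min(ests), 1e-3)
})

test_that("confidence intervals bracket the estimate at 1.96 SE", {
  h <- make_h(c(0.5, 0.4, 0.3), rep(0.05, 3), c(0.1, 0.09, 0.05),
              rep(0.02, 3))
  for (est in list(ivw(h), mr_egger(h)$slope,
                   weighted_median(h, n_boot = 20, seed = 1))) {
    expect_equal(est$ci_low, est$beta - 1.96 * est$se)
    expect_equal(est$ci_high, est$beta + 1.96 * est$se)
    expect_true(est$ci_low <= est$beta && est$beta <= est$ci_high)
  }
})
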