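test_that("Wald ratio arithmetic and degenerate cases", {
  p <- make_pairs(0.5, 0.1, se_out = 0.05)
  est <- wald_ratio(p)
  expect_equal(est$beta, 0.2)
  expect_equal(est$se, 0.1)
  expect_equal(est$or, exp(0.2))

  null <- wald_ratio(make_pairs(0.5, 0))
  expect_equal(null$beta, 0)
  expect_equal(null$or, 1)

  expect_error(wald_ratio(make_pairs(0, 0.1)), "zero")
  # second-order se exceeds first-order
  expect_gt(wald_ratio(p, second_order = TRUE)$se, est$se - 1e-12)
})

test_that("IVW pools ratios with inverse-variance weights", {
  # two identical ratios: same estimate, se shrinks by sqrt(2)
  single <- wald_ratio(make_pairs(0.5, 0.1, se_out = 0.05))
  pooled <- mr_ivw(make_pairs(c(0.5, 0.5), c(0.1, 0.1), se_out = 0.05))
  expect_equal(pooled$beta, single$beta)
  expect_equal(pooled$se, single$se / sqrt(2))
  # k copies generally
  k <- 5
  pk <- mr_ivw(make_pairs(rep(0.5, k), rep(0.1, k), se_out = 0.05))
  expect_equal(pk$se, single$se / sqrt(k))

  expect_error(mr_ivw(make_pairs(0.5, 0.1)), "wald_ratio")

  # oracle: weighted least squares of ratios through the origin
  set.seed(3)
  for (i in 1:20) {
    n <- sample(3:15, 1)
    p <- make_pairs(runif(n, 0.1, 0.5), rnorm(n, 0.1, 0.05),
                    se_out = runif(n, 0.01, 0.1))
    theta <- p$beta_out / p$beta_exp
    se <- p$se_out / abs(p$beta_exp)
    fit <- lm(theta ~ 0 + rep(1, n), weights = 1 / se^2)
    got <- mr_ivw(p)
    expect_equal(got$beta, unname(coef(fit)), tolerance = 1e-10)
  }
})

test_that("Egger regression recovers slope and directional pleiotropy", {
  set.seed(9)
  n <- 50
  bx <- runif(n, 0.1, 0.5)
  se_out <- rep(0.02, n)
  delta <- 0.05
  by <- 0.3 * bx + delta + rnorm(n, 0, se_out)
  e <- mr_egger(make_pairs(bx, by, se_out = se_out))
  expect_equal(e$estimate$beta, 0.3, tolerance = 0.1)
  expect_equal(e$intercept$value, delta, tolerance = 0.02)
  expect_lt(e$intercept$pval, 0.05)

  # no pleiotropy: intercept near zero
  by0 <- 0.3 * bx + rnorm(n, 0, se_out)
  e0 <- mr_egger(make_pairs(bx, by0, se_out = se_out))
  expect_equal(e0$intercept$value, 0, tolerance = 0.02)

  expect_error(mr_egger(make_pairs(c(0.3, 0.3, 0.3), c(0.1, 0.1, 0.1))),
               "collinear")
  expect_error(mr_egger(make_pairs(c(0.3, 0.2), c(0.1, 0.1))), ">= 3")
})

test_that("weighted median interpolates under cumulative weights", {
  p <- make_pairs(c(1, 1, 1), c(0.1, 0.2, 0.3), se_out = 0.05)
  wm <- mr_weighted_median(p, nboot = 200, seed = 4)
  expect_equal(wm$beta, 0.2, tolerance = 1e-9)
  expect_gt(wm$se, 0)

  # robustness: 60% valid instruments at theta, 40% outliers
  hits <- 0
  for (seed in 1:10) {
    set.seed(seed)
    n <- 10
    bx <- runif(n, 0.2, 0.5)
    by <- 0.3 * bx + rnorm(n, 0, 0.02)
    by[1:4] <- by[1:4] + 0.5  # invalid instruments
    p <- make_pairs(bx, by, se_out = 0.02)
    wm <- mr_weighted_median(p, nboot = 100, seed = seed)$beta
    ivw <- mr_ivw(p)$beta
    if (abs(wm - 0.3) < abs(ivw - 0.3)) hits <- hits + 1
  }
  expect_gt(hits, 5)
})

test_that("mode estimators find the dominant ratio cluster", {
  set.seed(12)
  n <- 15
  bx <- runif(n, 0.2, 0.5)
  by <- 0.3 * bx + rnorm(n, 0, 0.01)
  by[1:3] <- by[1:3] + 0.4
  p <- make_pairs(bx, by, se_out = 0.01)
  sm <- mr_simple_mode(p, nboot = 100, seed = 1)
  wmode <- mr_weighted_mode(p, nboot = 100, seed = 1)
  expect_equal(sm$beta, 0.3, tolerance = 0.07)
  expect_equal(wmode$beta, 0.3, tolerance = 0.07)

  # all ratios identical: every estimator returns that value
  pid <- make_pairs(c(0.5, 0.4, 0.2), c(0.15, 0.12, 0.06), se_out = 0.03)
  for (f in list(mr_ivw,
                 function(x) mr_weighted_median(x, nboot = 50, seed = 1),
                 function(x) mr_simple_mode(x, nboot = 50, seed = 1),
                 function(x) mr_weighted_mode(x, nboot = 50, seed = 1)))
    expect_equal(f(pid)$beta, 0.3, tolerance = 1e-6)
})

test_that("Cochran's Q detects heterogeneity and is null-calibrated", {
  # two identical ratios: Q = 0, p = 1
  q0 <- cochran_q(make_pairs(c(0.5, 0.5), c(0.1, 0.1), se_out = 0.05))
  expect_equal(q0$q, 0)
  expect_equal(q0$pval, 1)
  expect_equal(q0$df, 1)

  # injected outlier: significant in the majority of seeds at 20 SNPs
  sig <- 0
  for (seed in 1:10) {
    set.seed(seed)
    bx <- runif(20, 0.2, 0.5)
    by <- 0.3 * bx + rnorm(20, 0, 0.02)
    by[1] <- by[1] + 0.3
    if (cochran_q(make_pairs(bx, by, se_out = 0.02))$pval < 0.05) sig <- sig + 1
  }
  expect_gte(sig, 6)

  # homogeneous simulated ratios: p roughly uniform (mean near 0.5)
  ps <- vapply(1:100, function(seed) {
    set.seed(seed + 1000)
    bx <- runif(10, 0.2, 0.5)
    by <- 0.3 * bx + rnorm(10, 0, 0.02)
    cochran_q(make_pairs(bx, by, se_out = 0.02))$pval
  }, numeric(1))
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})

test_that("mr_fit dispatches on instrument count and exposes diagnostics", {
  p1 <- make_pairs(0.5, 0.1, se_out = 0.05)
  f1 <- mr_fit(p1)
  expect_equal(f1$results$method, "wald_ratio")
  expect_null(f1$heterogeneity)

  p2 <- make_pairs(c(0.5, 0.4), c(0.1, 0.09), se_out = 0.05)
  f2 <- mr_fit(p2)
  expect_equal(f2$results$method, "ivw")
  expect_false(is.null(f2$heterogeneity))

  set.seed(2)
  bx <- runif(8, 0.2, 0.5)
  p8 <- make_pairs(bx, 0.3 * bx + rnorm(8, 0, 0.02), se_out = 0.02)
  f8 <- mr_fit(p8, nboot = 100, seed = 5)
  expect_setequal(f8$results$method,
                  c("ivw", "egger", "weighted_median", "simple_mode",
                    "weighted_mode"))
  expect_false(is.null(f8$pleiotropy))
  expect_named(coef(f8))
  ci <- confint(f8)
  expect_true(all(ci[, "lower"] <= coef(f8) + 1e-12))
  expect_error(mr_fit(p2, methods = "egger"), "more instruments")
  expect_output(print(summary(f8)), "Heterogeneity")

  # bootstrap is seed-deterministic
  expect_identical(mr_fit(p8, nboot = 100, seed = 5)$results,
                   f8$results)
})
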