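test_that("fixed-effect pooling matches the weighted-average oracle", {
  p <- pool_fixed(c(0.2, 0.6), c(0.04, 0.04))
  expect_equal(p$mu, 0.4)
  expect_equal(p$se, sqrt(0.02))

  p2 <- pool_fixed(rep(0.3, 4), c(0.1, 0.2, 0.3, 0.4))
  expect_equal(p2$mu, 0.3)
  expect_equal(p2$het$Q, 0)
  expect_equal(p2$het$I2, 0)

  set.seed(5)
  y <- rnorm(5); v <- runif(5, 0.01, 0.5)
  o <- oracle_weighted_mean(y, v)
  p3 <- pool_fixed(y, v)
  expect_equal(p3$mu, o$mu, tolerance = 1e-12)
  expect_equal(p3$se, o$se, tolerance = 1e-12)

  expect_error(pool_fixed(0.2, 0.1), "at least 2")
})

test_that("DerSimonian-Laird tau2 matches hand computation", {
  expect_identical(tau2_dl(rep(0.5, 5), rep(0.2, 5)), 0)
  # w = 1 each: Q = 2, df = 1, denominator = 2 - 1
  expect_equal(tau2_dl(c(0, 2), c(1, 1)), 1)
  # scaling: with all v scaled by c, Q and the denominator rescale per the
  # formula; check against the definition written out directly
  set.seed(6)
  y <- rnorm(6, 0, 1); v <- runif(6, 0.05, 0.3)
  for (cc in c(0.5, 2)) {
    w <- 1 / (v * cc)
    mu <- sum(w * y) / sum(w)
    q <- sum(w * (y - mu)^2)
    expected <- max(0, (q - 5) / (sum(w) - sum(w^2) / sum(w)))
    expect_equal(tau2_dl(y, v * cc), expected, tolerance = 1e-12)
  }
})

test_that("three-study heterogeneity statistics match frozen hand values", {
  y <- c(0.1, 0.5, 0.9)
  v <- c(0.04, 0.09, 0.16)
  p <- pool_fixed(y, v)
  expect_equal(p$mu, 0.3229508196721311, tolerance = 1e-10)
  expect_equal(p$het$Q, 3.672131147540984, tolerance = 1e-10)
  expect_equal(p$het$I2, 45.53571428571428, tolerance = 1e-10)
  expect_equal(tau2_dl(y, v), 0.07034482758620689, tolerance = 1e-10)
})

test_that("REML tau2 agrees with dense grid search", {
  fixtures <- list(
    list(y = c(0.1, 0.5, 0.9, 0.2, -0.3), v = rep(0.04, 5)),
    list(y = c(-0.2, 0.0, 0.15, 0.4, 0.9, 1.4), v = c(0.02, 0.05, 0.1, 0.04, 0.08, 0.06)),
    list(y = c(0.3, 0.32, 0.28, 0.31), v = c(0.01, 0.02, 0.015, 0.01)))
  for (f in fixtures) {
    expect_equal(tau2_reml(f$y, f$v), oracle_reml_grid(f$y, f$v),
                 tolerance = 2e-4)
  }
  # with a moderator design
  x <- c(0, 0, 1, 1, 0, 1)
  f <- fixtures[[2]]
  X <- cbind(1, x)
  expect_equal(tau2_reml(f$y, f$v, X), oracle_reml_grid(f$y, f$v, X),
               tolerance = 2e-4)
})

test_that("REML recovers simulated heterogeneity", {
  set.seed(21)
  # no heterogeneity: estimates concentrate near zero
  t0 <- replicate(40, {
    v <- runif(40, 0.02, 0.1)
    tau2_reml(rnorm(40, 0.3, sqrt(v)), v)
  })
  expect_lt(median(t0), 0.01)
  # tau = 0.3 with many studies: recovered within Monte-Carlo error
  v <- runif(200, 0.02, 0.1)
  y <- rnorm(200, 0.3, sqrt(v + 0.09))
  expect_lt(abs(tau2_reml(y, v) - 0.09), 0.04)
})

test_that("random-effects pooling collapses to fixed at tau2 = 0", {
  y <- rep(0.4, 4); v <- c(0.1, 0.2, 0.1, 0.3)   # REML tau2 is exactly 0
  pr <- pool_random(y, v)
  pf <- pool_fixed(y, v)
  expect_identical(pr$mu, pf$mu)
  expect_identical(pr$se, pf$se)
  expect_identical(pr$ci_low, pf$ci_low)
  expect_identical(pr$het$tau2, 0)
})

test_that("random-effects pooling widens with heterogeneity", {
  y <- c(-0.8, 0.1, 0.9, 1.6, -1.2)
  v <- c(0.02, 0.03, 0.02, 0.05, 0.04)
  pr <- pool_random(y, v)
  pf <- pool_fixed(y, v)
  expect_gte(pr$se, pf$se)
  expect_gt(pr$het$tau2, 0)
  # equal sampling variances: mu is the unweighted mean under any tau2
  y2 <- c(0.1, 0.4, 0.7, 1.9)
  pr2 <- pool_random(y2, rep(0.05, 4))
  expect_equal(pr2$mu, mean(y2), tolerance = 1e-12)
})

test_that("meta-regression recovers saturated group means", {
  y <- c(0, 0, 0.5)
  v <- rep(0.04, 3)
  x <- c(0, 0, 1)
  fit <- meta_regress(y, v, x, tau2_fixed = 0)
  expect_equal(unname(fit$coef), c(0, 0.5), tolerance = 1e-12)
  # location equivariance of the slope
  fit2 <- meta_regress(y + 3, v, x, tau2_fixed = 0)
  expect_equal(fit2$coef[["moderator"]], fit$coef[["moderator"]],
               tolerance = 1e-12)
  expect_error(meta_regress(y, v, c(1, 1, 1)), "constant")
})

test_that("intercept-only meta-regression reproduces random-effects pooling", {
  set.seed(31)
  y <- rnorm(8, 0.3, 0.4); v <- runif(8, 0.02, 0.2)
  fit <- meta_regress(y, v)
  pr <- pool_random(y, v)
  expect_equal(fit$coef[["intercept"]], pr$mu, tolerance = 1e-10)
  expect_equal(sqrt(fit$cov[1, 1]), pr$se, tolerance = 1e-10)
})

test_that("engine agrees with metafor on pooled fits and meta-regression", {
  library(metafor)
  set.seed(41)
  y <- rnorm(9, 0.2, 0.5); v <- runif(9, 0.02, 0.3)
  x <- rep(c(0, 1), length.out = 9)

  # the two REML optimizers converge independently; agreement to ~1e-4
  pr <- pool_random(y, v, "reml")
  rm <- rma(yi = y, vi = v, method = "REML", test = "z")
  expect_lt(abs(pr$mu - unname(coef(rm))), 1e-5)
  expect_lt(abs(pr$het$tau2 - rm$tau2), 1e-4)
  expect_lt(abs(pr$se - rm$se), 1e-5)

  pd <- pool_random(y, v, "dl")
  rd <- rma(yi = y, vi = v, method = "DL", test = "z")
  expect_equal(pd$het$tau2, rd$tau2, tolerance = 1e-10)

  mr <- meta_regress(y, v, x, "reml")
  rr <- rma(yi = y, vi = v, mods = ~x, method = "REML", test = "z")
  expect_lt(abs(mr$coef[["moderator"]] - unname(coef(rr)[2])), 1e-4)
  expect_lt(abs(mr$se[[2]] - rr$se[2]), 1e-4)
  expect_lt(abs(mr$tau2 - rr$tau2), 1e-4)
})
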