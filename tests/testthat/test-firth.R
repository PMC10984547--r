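sep2x2 <- data.frame(x = c(0, 0, 0, 0, 1, 1, 1, 1),
                     y = c(0, 0, 0, 0, 1, 1, 1, 1))

test_that("Firth estimates are finite under separation and match the grid oracle", {
  X <- cbind(1, sep2x2$x)
  fit <- fit_firth(X, sep2x2$y)
  expect_true(all(is.finite(fit$beta)))
  gb <- oracle_firth_grid(X, sep2x2$y)
  expect_lt(max(abs(fit$beta - gb)), 1e-3)
  # plain MLE diverges on the same data: coefficients run away
  mle <- suppressWarnings(glm(y ~ x, binomial, sep2x2))
  expect_gt(max(abs(coef(mle))), 10)
})

test_that("Firth matches the grid oracle on non-separated two-parameter fits", {
  set.seed(51)
  for (i in 1:4) {
    x <- rnorm(30)
    y <- rbinom(30, 1, plogis(0.3 + 0.8 * x))
    if (sum(y) == 0 || sum(y) == 30) next
    X <- cbind(1, x)
    fit <- fit_firth(X, y)
    gb <- oracle_firth_grid(X, y)
    expect_lt(max(abs(fit$beta - gb)), 1e-3)
  }
})

test_that("penalized intercept-only fit has the closed-form shrunk rate", {
  # penalized binomial: pi_hat = (k + 1/2) / (n + 1)
  for (kn in list(c(3, 10), c(0, 12), c(5, 9))) {
    y <- rep(c(1, 0), c(kn[1], kn[2] - kn[1]))
    if (kn[1] == 0) {
      # all non-events is rejected by design (no information on the event)
      expect_error(fit_firth(matrix(1, kn[2], 1), y), "at least one event")
    } else {
      fit <- fit_firth(matrix(1, kn[2], 1), y)
      expect_equal(plogis(fit$beta), (kn[1] + 0.5) / (kn[2] + 1),
                   tolerance = 1e-8)
    }
  }
})

test_that("Firth slope is near zero on balanced null data", {
  set.seed(52)
  x <- rep(c(0, 1), each = 1000)
  y <- rbinom(2000, 1, 0.5)
  fit <- fit_firth(cbind(1, x), y)
  expect_lt(abs(fit$beta[2]), 0.15)
})

test_that("profile CI is symmetric on a symmetric table and nests by level", {
  d <- data.frame(x = rep(c(0, 1), each = 10), y = rep(c(1, 0, 1, 0), each = 5))
  f95 <- firth_logistic(y ~ x, d)
  expect_equal(f95$ci_low[2], -f95$ci_high[2], tolerance = 1e-4)
  f90 <- firth_logistic(y ~ x, d, level = 0.90)
  expect_gt(f90$ci_low[2], f95$ci_low[2])
  expect_lt(f90$ci_high[2], f95$ci_high[2])
})

test_that("profile CI on separated data is finite and matches the grid profile", {
  f <- firth_logistic(y ~ x, sep2x2)
  expect_true(all(f$ci_finite[2, ]))
  bounds <- oracle_profile_bounds(cbind(1, sep2x2$x), sep2x2$y, j = 2)
  expect_lt(abs(log(f$or[2] / exp(coef(f)[2]))), 1e-10)  # or = exp(beta)
  expect_lt(abs(f$ci_low[2] - bounds[1]), 0.01)
  expect_lt(abs(f$ci_high[2] - bounds[2]), 0.01)
})

test_that("profile CI / p-value duality holds exactly", {
  sets <- list(
    sep2x2,
    data.frame(x = rep(c(0, 1), each = 10), y = rep(c(1, 0, 1, 0), each = 5)),
    data.frame(x = rep(c(0, 1), c(9, 20)),
               y = rep(c(1, 0, 1, 0), c(5, 4, 16, 4))))
  for (d in sets) {
    f <- firth_logistic(y ~ x, d)
    for (j in 1:2) {
      excludes0 <- f$ci_low[j] > 0 || f$ci_high[j] < 0
      expect_identical(f$p_values[j] < 0.05, excludes0)
    }
  }
})

test_that("penalized likelihood-ratio p-values are approximately uniform under the null", {
  set.seed(53)
  pv <- replicate(1000, {
    x <- rnorm(60)
    y <- rbinom(60, 1, 0.5)
    X <- cbind(1, x)
    fit <- fit_firth(X, y)
    plr_pvalue(X, y, fit, 2)
  })
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})

test_that("Firth and MLE agree on large well-separated-free samples", {
  set.seed(54)
  x <- rnorm(5000)
  y <- rbinom(5000, 1, plogis(0.2 + 0.5 * x))
  ff <- fit_firth(cbind(1, x), y)
  mle <- glm.fit(cbind(1, x), y, family = binomial())
  expect_lt(max(abs(ff$beta - mle$coefficients)), 0.02)
})

test_that("2x2 univariate fit equals the cross-product identity", {
  f <- fit_mle_2x2(16, 4, 5, 4)
  expect_equal(f$or[["exposure"]], 3.2, tolerance = 1e-12)
  expect_equal(fit_mle_2x2(3, 3, 3, 3)$or[["exposure"]], 1)
  # iterative logistic fit agrees with the identity
  f2 <- fit_mle_2x2(1, 1, 1, 2)
  expect_equal(f2$or[["exposure"]], 2, tolerance = 1e-12)
  g <- glm(y ~ x, binomial,
           data.frame(x = rep(c(1, 1, 0, 0), c(1, 1, 1, 2)),
                      y = rep(c(1, 0, 1, 0), c(1, 1, 1, 2))))
  expect_equal(unname(exp(coef(g)[2])), 2, tolerance = 1e-8)
  expect_error(fit_mle_2x2(5, 0, 3, 2), "firth_logistic")
})

test_that("rank-deficient designs are rejected with the offending columns named", {
  x <- rnorm(20)
  X <- cbind(intercept = 1, a = x, b = 2 * x)
  y <- rbinom(20, 1, 0.5)
  y[1] <- 1; y[2] <- 0
  expect_error(fit_firth(X, y), "collinear")
})
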