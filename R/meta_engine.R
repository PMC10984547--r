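# Inverse-variance pooling, heterogeneity estimation and weighted
# meta-regression, implemented from the standard formulas. The two-stage
# language-bias estimator in metaepi.R is built on these primitives.

het_stats <- function(y, v, tau2 = 0) {
  w <- 1 / v
  mu <- sum(w * y) / sum(w)
  q <- sum(w * (y - mu)^2)
  df <- length(y) - 1L
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  list(Q = q, df = df, I2 = i2, tau2 = tau2, tau = sqrt(tau2))
}

#' DerSimonian-Laird between-study variance
#'
#' Moment estimator \eqn{\hat\tau^2 = \max(0, (Q - df)/(\sum w_i - \sum
#' w_i^2/\sum w_i))} with fixed-effect weights \eqn{w_i = 1/v_i}.
#'
#' @param y effect estimates.
#' @param v their sampling variances (all positive).
#' @return non-negative scalar.
#' @export
tau2_dl <- function(y, v) {
  stopifnot(length(y) == length(v), length(y) >= 2, all(v > 0))
  w <- 1 / v
  mu <- sum(w * y) / sum(w)
  q <- sum(w * (y - mu)^2)
  df <- length(y) - 1
  denom <- sum(w) - sum(w^2) / sum(w)
  max(0, (q - df) / denom)
}

# Restricted log-likelihood of the additive random-effects model
# y ~ N(X beta, v + tau2), up to a constant.
reml_ll <- function(tau2, y, v, X) {
  vt <- v + tau2
  w <- 1 / vt
  xw <- X * w
  m <- crossprod(X, xw)
  beta <- solve(m, crossprod(xw, y))
  r <- y - X %*% beta
  -0.5 * (sum(log(vt)) + determinant(m)$modulus[1] + sum(w * r^2))
}

#' REML between-study variance
#'
#' Maximizes the restricted log-likelihood of the model
#' \eqn{y_i \sim N(x_i^\top\beta,\; v_i + \tau^2)} over \eqn{\tau^2 \ge 0}
#' by bounded scalar search on \[0, 100\] (tolerance 1e-8, deterministic).
#'
#' @param y effect estimates.
#' @param v their sampling variances.
#' @param X moderator design matrix including the intercept; defaults to
#'   intercept-only.
#' @return non-negative scalar.
#' @export
tau2_reml <- function(y, v, X = NULL) {
  stopifnot(length(y) == length(v), all(v > 0))
  if (is.null(X)) X <- matrix(1, length(y), 1)
  X <- as.matrix(X)
  if (length(y) < ncol(X) + 1) {
    stop("need at least ", ncol(X) + 1, " effects for ", ncol(X),
         " design columns")
  }
  opt <- stats::optimize(reml_ll, c(0, 100), y = y, v = v, X = X,
                         maximum = TRUE, tol = 1e-8)
  # the boundary tau2 = 0 is never an interior point of the search
  if (reml_ll(0, y, v, X) >= opt$objective) 0 else opt$maximum
}

pooled_estimate <- function(y, v, tau2, model, het_tau2 = tau2) {
  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- mu / se
  zq <- stats::qnorm(0.975)
  structure(
    list(mu = mu, se = se, ci_low = mu - zq * se, ci_high = mu + zq * se,
         p_value = 2 * stats::pnorm(-abs(z)), model = model, k = length(y),
         het = het_stats(y, v, het_tau2)),
    class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("%s-effect%s pooled estimate: %.4f (95%% CI %.4f to %.4f), p = %.4g\n",
              if (x$model == "fixed") "fixed" else "random",
              if (x$model == "fixed") "" else "s",
              x$mu, x$ci_low, x$ci_high, x$p_value))
  cat(sprintf("k = %d; Q = %.4f (df = %d), I2 = %.1f%%, tau2 = %.4f\n",
              x$k, x$het$Q, x$het$df, x$het$I2, x$het$tau2))
  invisible(x)
}

#' Fixed-effect inverse-variance pooling
#'
#' Weights \eqn{w_i = 1/v_i}; pooled mean \eqn{\sum w_i y_i / \sum w_i},
#' standard error \eqn{\sqrt{1/\sum w_i}}, two-sided normal p-value.
#'
#' @inheritParams tau2_dl
#' @return object of class `pooled_estimate` with elements `mu`, `se`,
#'   `ci_low`, `ci_high`, `p_value`, `model`, `k` and `het` (Q, df, I2, tau2).
#'   Under the fixed model `het$tau2` is 0 (the weights assume no
#'   between-study variance); Q and I2 still describe observed heterogeneity.
#' @export
pool_fixed <- function(y, v) {
  if (length(y) < 2) stop("need at least 2 effects to pool")
  stopifnot(length(y) == length(v), all(v > 0))
  pooled_estimate(y, v, tau2 = 0, model = "fixed", het_tau2 = 0)
}

#' Random-effects inverse-variance pooling
#'
#' As [pool_fixed()] but with weights \eqn{w_i^* = 1/(v_i + \hat\tau^2)},
#' the between-study variance estimated by REML (default) or
#' DerSimonian-Laird.
#'
#' @inheritParams tau2_dl
#' @param tau2_method `"reml"` or `"dl"`.
#' @return object of class `pooled_estimate`; `het$tau2` holds the estimate.
#' @export
pool_random <- function(y, v, tau2_method = c("reml", "dl")) {
  if (length(y) < 2) stop("need at least 2 effects to pool")
  stopifnot(length(y) == length(v), all(v > 0))
  tau2_method <- match.arg(tau2_method)
  t2 <- if (tau2_method == "reml") tau2_reml(y, v) else tau2_dl(y, v)
  pooled_estimate(y, v, tau2 = t2, model = "random")
}

#' Weighted meta-regression on a binary moderator
#'
#' Fits \eqn{y_i = \beta_0 + \beta_1 x_i + u_i + e_i} with
#' \eqn{u_i \sim N(0, \tau^2)}, \eqn{e_i \sim N(0, v_i)}:
#' \eqn{\hat\beta = (X^\top W X)^{-1} X^\top W y} with
#' \eqn{W = \mathrm{diag}(1/(v_i+\hat\tau^2))} and covariance
#' \eqn{(X^\top W X)^{-1}}. With the non-English indicator as moderator the
#' slope is the within-meta-analysis difference in SMD (dSMD).
#'
#' For `tau2_method = "dl"` the moment estimator is generalized to the
#' regression design: \eqn{\hat\tau^2 = \max(0, (Q_E - (k-p))/\mathrm{tr}(P))}
#' with \eqn{P = W_F - W_F X (X^\top W_F X)^{-1} X^\top W_F},
#' \eqn{W_F = \mathrm{diag}(1/v_i)}, which reduces to [tau2_dl()] for the
#' intercept-only design.
#'
#' @inheritParams tau2_dl
#' @param x moderator; must take at least two distinct values (omit `x` or
#'   pass `NULL` for an intercept-only model).
#' @param tau2_method `"reml"` or `"dl"`.
#' @param tau2_fixed optional known value of tau2 overriding estimation.
#' @return list with `coef` (named vector), `cov`, `se`, `tau2` and `het`
#'   (residual Q with df = k - p, I2, tau2).
#' @export
meta_regress <- function(y, v, x = NULL, tau2_method = c("reml", "dl"),
                         tau2_fixed = NULL) {
  stopifnot(length(y) == length(v), all(v > 0))
  tau2_method <- match.arg(tau2_method)
  if (is.null(x)) {
    X <- matrix(1, length(y), 1, dimnames = list(NULL, "intercept"))
  } else {
    if (length(unique(x)) < 2) {
      stop("moderator is constant: no non-English contrast estimable")
    }
    stopifnot(length(x) == length(y))
    X <- cbind(intercept = 1, moderator = as.numeric(x))
  }
  k <- length(y)
  p <- ncol(X)
  if (k < p + 1) stop("need at least ", p + 1, " effects")
  t2 <- if (!is.null(tau2_fixed)) {
    tau2_fixed
  } else if (tau2_method == "reml") {
    tau2_reml(y, v, X)
  } else {
    wf <- 1 / v
    xw <- X * wf
    m <- solve(crossprod(X, xw))
    bf <- m %*% crossprod(xw, y)
    qe <- sum(wf * (y - X %*% bf)^2)
    trp <- sum(wf) - sum(diag(m %*% crossprod(xw, xw)))
    max(0, (qe - (k - p)) / trp)
  }
  w <- 1 / (v + t2)
  xw <- X * w
  covb <- solve(crossprod(X, xw))
  beta <- drop(covb %*% crossprod(xw, y))
  names(beta) <- colnames(X)
  # residual heterogeneity on fixed-effect weights
  wf <- 1 / v
  xwf <- X * wf
  bf <- solve(crossprod(X, xwf), crossprod(xwf, y))
  qe <- sum(wf * (y - X %*% bf)^2)
  dfe <- k - p
  i2 <- if (qe > 0) max(0, (qe - dfe) / qe) * 100 else 0
  list(coef = beta, cov = covb, se = sqrt(diag(covb)), tau2 = t2,
       het = list(Q = qe, df = dfe, I2 = i2, tau2 = t2, tau = sqrt(t2)))
}
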