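# Bias-reduced (Firth) binary logistic regression with profile
# penalized-likelihood inference, plus a plain-MLE mode and the closed-form
# 2x2 fit. The Jeffreys-prior penalty 0.5 * log det I(beta) keeps estimates
# finite under complete or quasi-separation, which arises in the
# review-characteristics table (levels with zero events).

log1pexp <- function(x) {
  # numerically stable log(1 + exp(x))
  ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))
}

penalized_loglik <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  vv <- pmax(p * (1 - p), .Machine$double.eps)
  info <- crossprod(X, X * vv)
  sum(y * eta) - sum(log1pexp(eta)) + 0.5 * determinant(info)$modulus[1]
}

# Modified-scoring Firth fit; `free` restricts updates to a coordinate
# subset (used for profiling), with the other coordinates held at their
# values in `start`.
firth_scoring <- function(X, y, start = NULL, free = seq_len(ncol(X)),
                          maxit = 100, tol_score = 1e-6, tol_step = 1e-8) {
  p <- ncol(X)
  beta <- if (is.null(start)) numeric(p) else start
  ll <- penalized_loglik(X, y, beta)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    pi <- stats::plogis(eta)
    vv <- pmax(pi * (1 - pi), .Machine$double.eps)
    info <- crossprod(X, X * vv)
    h <- vv * rowSums((X %*% solve(info)) * X)
    score <- drop(crossprod(X, y - pi + h * (0.5 - pi)))
    uf <- score[free]
    step <- numeric(p)
    step[free] <- solve(info[free, free, drop = FALSE], uf)
    # safeguarded step: halve until the penalized likelihood does not drop
    fac <- 1
    repeat {
      cand <- beta + fac * step
      llc <- penalized_loglik(X, y, cand)
      if (llc >= ll - 1e-10 || fac < 1e-4) break
      fac <- fac / 2
    }
    beta <- beta + fac * step
    ll <- llc
    if (max(abs(uf)) < tol_score && max(abs(fac * step)) < tol_step) {
      converged <- TRUE
      break
    }
  }
  if (!converged && max(abs(uf)) >= tol_score) {
    stop("Firth scoring did not converge within ", maxit,
         " iterations (max |score| = ", signif(max(abs(uf)), 3), ")")
  }
  eta <- drop(X %*% beta)
  pi <- stats::plogis(eta)
  vv <- pmax(pi * (1 - pi), .Machine$double.eps)
  list(beta = beta, loglik = ll, info = crossprod(X, X * vv),
       iterations = it, converged = TRUE)
}

check_design <- function(X, y) {
  stopifnot(nrow(X) == length(y))
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1")
  if (sum(y) == 0 || sum(y) == length(y)) {
    stop("need at least one event and one non-event")
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq(qx$rank + 1, ncol(X))]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Firth penalized-likelihood logistic fit (matrix interface)
#'
#' Maximizes \eqn{l^*(\beta) = l(\beta) + \frac12 \log\det I(\beta)} (the
#' Jeffreys-prior penalized log-likelihood) by modified Fisher scoring with
#' hat-value adjusted responses and step-halving. Estimates are finite even
#' under separation.
#'
#' @param X design matrix including the intercept column.
#' @param y binary 0/1 response.
#' @param maxit iteration cap.
#' @return list with `beta`, `loglik` (penalized), `info` (Fisher
#'   information at the optimum), `iterations`, `converged`.
#' @export
fit_firth <- function(X, y, maxit = 100) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  check_design(X, y)
  firth_scoring(X, y, maxit = maxit)
}

profile_loglik <- function(X, y, j, value, start) {
  start[j] <- value
  free <- setdiff(seq_len(ncol(X)), j)
  out <- tryCatch(
    firth_scoring(X, y, start = start, free = free)$loglik,
    error = function(e) NULL)
  if (!is.null(out)) return(out)
  # far out in the tails the scoring step becomes numerically unstable
  # (fitted probabilities collapse to 0/1); fall back to direct
  # maximization of the penalized likelihood over the free coordinates
  fn <- function(bf) {
    b <- start
    b[free] <- bf
    -penalized_loglik(X, y, b)
  }
  opt <- stats::optim(start[free], fn, method = "BFGS",
                      control = list(maxit = 500))
  if (length(free) > 0 && opt$convergence != 0) {
    opt2 <- stats::optim(opt$par, fn, method = "Nelder-Mead",
                         control = list(maxit = 2000))
    if (opt2$value < opt$value) opt <- opt2
  }
  -opt$value
}

#' Profile penalized-likelihood confidence interval
#'
#' The bounds are the values of the j-th coefficient where twice the drop in
#' the profiled penalized log-likelihood equals the chi-squared(1) quantile.
#' Root finding is by bracketing plus bisection (tolerance 1e-6); a bound is
#' reported as infinite (and flagged) only when the profile never crosses the
#' threshold within +/- 50 on the log-odds scale.
#'
#' @param X,y design matrix and binary response.
#' @param fit a converged [fit_firth()] result on `X`, `y`.
#' @param j coefficient index.
#' @param level confidence level.
#' @return list with `low`, `high` and `finite` (logical length 2).
#' @export
profile_ci <- function(X, y, fit, j, level = 0.95) {
  X <- as.matrix(X)
  thresh <- fit$loglik - stats::qchisq(level, 1) / 2
  se <- sqrt(diag(solve(fit$info)))[j]
  if (!is.finite(se) || se <= 0) se <- 1
  bhat <- fit$beta[j]
  f <- function(b) profile_loglik(X, y, j, b, fit$beta) - thresh

  bound <- function(direction) {
    step <- direction * se
    b <- bhat
    for (m in seq_len(200)) {
      b2 <- bhat + m * step
      if (abs(b2) > 50) return(list(value = direction * Inf, finite = FALSE))
      if (f(b2) < 0) {
        r <- stats::uniroot(f, sort(c(b, b2)), tol = 1e-6)
        return(list(value = r$root, finite = TRUE))
      }
      b <- b2
    }
    list(value = direction * Inf, finite = FALSE)
  }
  lo <- bound(-1)
  hi <- bound(1)
  list(low = lo$value, high = hi$value, finite = c(lo$finite, hi$finite))
}

#' Penalized likelihood-ratio p-value
#'
#' \eqn{p = 1 - F_{\chi^2_1}(2[l^*(\hat\beta) - l^*_{\beta_j = 0}])}. By
#' construction p < 0.05 exactly when the 0.95 profile interval of
#' [profile_ci()] excludes 0 (same likelihood-ratio machinery).
#'
#' @inheritParams profile_ci
#' @return p-value in \[0, 1\].
#' @export
plr_pvalue <- function(X, y, fit, j) {
  X <- as.matrix(X)
  ll0 <- profile_loglik(X, y, j, 0, fit$beta)
  stat <- max(0, 2 * (fit$loglik - ll0))
  stats::pchisq(stat, 1, lower.tail = FALSE)
}

#' Logistic regression with Firth bias reduction (formula interface)
#'
#' Fits a binary logistic regression by penalized maximum likelihood
#' (`method = "firth"`, default) with profile penalized-likelihood
#' confidence intervals and likelihood-ratio p-values, or by plain maximum
#' likelihood (`method = "mle"`, via [stats::glm()]) with Wald inference.
#'
#' @param formula model formula; the response may be logical, 0/1 numeric,
#'   or a two-level factor (second level = event).
#' @param data data frame.
#' @param method `"firth"` or `"mle"`.
#' @param level confidence level for the reported intervals.
#' @param maxit iteration cap for the penalized fit.
#' @return object of class `firthfit` with `coefficients`, `or` (odds
#'   ratios), `ci_low`, `ci_high`, `p_values`, `vcov`, `loglik`, `method`,
#'   `converged`, `ci_finite`. Methods: `print`, `summary`, `coef`,
#'   `confint`, `vcov`, `predict`, `residuals`.
#' @examples
#' d <- data.frame(x = c(0, 0, 0, 0, 1, 1, 1, 1),
#'                 y = c(0, 0, 0, 1, 0, 1, 1, 1))
#' firth_logistic(y ~ x, d)
#' @export
firth_logistic <- function(formula, data, method = c("firth", "mle"),
                           level = 0.95, maxit = 100) {
  method <- match.arg(method)
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  X <- stats::model.matrix(stats::terms(mf), mf)
  yr <- stats::model.response(mf)
  y <- if (is.factor(yr)) as.numeric(yr) - 1 else as.numeric(yr)
  zq <- stats::qnorm(1 - (1 - level) / 2)

  if (method == "firth") {
    check_design(X, y)
    fit <- firth_scoring(X, y, maxit = maxit)
    p <- ncol(X)
    ci_low <- ci_high <- pv <- numeric(p)
    fin <- matrix(TRUE, p, 2)
    for (j in seq_len(p)) {
      ci <- profile_ci(X, y, fit, j, level)
      ci_low[j] <- ci$low
      ci_high[j] <- ci$high
      fin[j, ] <- ci$finite
      pv[j] <- plr_pvalue(X, y, fit, j)
    }
    beta <- fit$beta
    vc <- solve(fit$info)
    ll <- fit$loglik
    converged <- fit$converged
  } else {
    gfit <- stats::glm.fit(X, y, family = stats::binomial())
    beta <- gfit$coefficients
    vc <- solve(crossprod(X, X * gfit$weights))
    se <- sqrt(diag(vc))
    ci_low <- beta - zq * se
    ci_high <- beta + zq * se
    pv <- 2 * stats::pnorm(-abs(beta / se))
    fin <- matrix(is.finite(cbind(ci_low, ci_high)), ncol(X), 2)
    ll <- sum(y * (X %*% beta) - log1pexp(drop(X %*% beta)))
    converged <- gfit$converged
  }
  names(beta) <- colnames(X)
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(
    list(coefficients = beta, or = exp(beta), ci_low = ci_low,
         ci_high = ci_high, p_values = pv, vcov = vc, loglik = ll,
         method = method, converged = converged, ci_finite = fin,
         level = level, X = X, y = y, coef_names = colnames(X)),
    class = "firthfit")
}

#' @export
print.firthfit <- function(x, digits = 3, ...) {
  cat(sprintf("Binary logistic regression (%s)%s\n",
              if (x$method == "firth") "Firth bias reduction" else "maximum likelihood",
              if (x$converged) "" else " [NOT CONVERGED]"))
  tab <- data.frame(beta = x$coefficients, OR = x$or,
                    ci_low = exp(x$ci_low), ci_high = exp(x$ci_high),
                    p = x$p_values, row.names = x$coef_names)
  print(round(tab, digits))
  cat(sprintf("CIs: %s, level %.2f; p-values: %s\n",
              if (x$method == "firth") "profile penalized likelihood" else "Wald",
              x$level,
              if (x$method == "firth") "penalized likelihood ratio" else "Wald"))
  invisible(x)
}

#' @export
summary.firthfit <- function(object, ...) object

#' @export
coef.firthfit <- function(object, ...) object$coefficients

#' @export
vcov.firthfit <- function(object, ...) object$vcov

#' @export
confint.firthfit <- function(object, parm, level, ...) {
  m <- cbind(low = object$ci_low, high = object$ci_high)
  rownames(m) <- object$coef_names
  if (!missing(parm)) m <- m[parm, , drop = FALSE]
  m
}

#' @export
predict.firthfit <- function(object, newdata = NULL,
                             type = c("link", "response"), ...) {
  type <- match.arg(type)
  X <- if (is.null(newdata)) object$X else
    stats::model.matrix(~., data = newdata)[, object$coef_names, drop = FALSE]
  eta <- drop(X %*% object$coefficients)
  if (type == "response") stats::plogis(eta) else eta
}

#' @export
residuals.firthfit <- function(object, ...) {
  object$y - stats::plogis(drop(object$X %*% object$coefficients))
}

#' Univariate logistic fit of a 2x2 table by the saturated-model identity
#'
#' For a 2x2 exposure-by-outcome table the maximum-likelihood slope equals
#' the log cross-product ratio exactly, so the odds ratio is
#' \eqn{(n_{11} n_{00})/(n_{10} n_{01})}; Wald standard error
#' \eqn{\sqrt{\sum 1/n_{ij}}}.
#'
#' @param n11 exposed with the event.
#' @param n10 exposed without the event.
#' @param n01 unexposed with the event.
#' @param n00 unexposed without the event.
#' @param level confidence level.
#' @return object of class `firthfit` (method `"mle"`); the second
#'   coefficient is the exposure log-odds ratio.
#' @examples
#' fit_mle_2x2(16, 4, 5, 4)$or[["exposure"]]  # 3.2
#' @export
fit_mle_2x2 <- function(n11, n10, n01, n00, level = 0.95) {
  cells <- c(n11, n10, n01, n00)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers")
  }
  if (n11 + n10 == 0 || n01 + n00 == 0 || n11 + n01 == 0 || n10 + n00 == 0) {
    stop("all table margins must be positive")
  }
  if (any(cells == 0)) {
    stop("zero cell: the MLE is not finite; use firth_logistic() instead")
  }
  beta <- c(intercept = log(n01 / n00),
            exposure = log((n11 * n00) / (n10 * n01)))
  vc <- matrix(c(1 / n01 + 1 / n00, -(1 / n01 + 1 / n00),
                 -(1 / n01 + 1 / n00), sum(1 / cells)), 2, 2,
               dimnames = list(names(beta), names(beta)))
  se <- sqrt(diag(vc))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  x <- rep(c(1, 1, 0, 0), cells)
  y <- rep(c(1, 0, 1, 0), cells)
  X <- cbind(intercept = 1, exposure = x)
  ll <- sum(y * (X %*% beta) - log1pexp(drop(X %*% beta)))
  structure(
    list(coefficients = beta, or = exp(beta), ci_low = beta - zq * se,
         ci_high = beta + zq * se,
         p_values = 2 * stats::pnorm(-abs(beta / se)), vcov = vc,
         loglik = ll, method = "mle", converged = TRUE,
         ci_finite = matrix(TRUE, 2, 2), level = level, X = X, y = y,
         coef_names = names(beta)),
    class = "firthfit")
}
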