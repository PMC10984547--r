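# Independent oracles used across the suite. These re-derive quantities
# from their definitions (closed forms, dense grids) without touching the
# package's own computational paths.

# inverse-variance weighted mean, written out directly
oracle_weighted_mean <- function(y, v) {
  w <- 1 / v
  list(mu = sum(w * y) / sum(w), se = sqrt(1 / sum(w)))
}

# restricted log-likelihood of y ~ N(X b, v + t2), independent algebra
oracle_reml_ll <- function(t2, y, v, design) {
  s2 <- v + t2
  W <- diag(1 / s2, length(y))
  M <- t(design) %*% W %*% design
  b <- solve(M) %*% t(design) %*% W %*% y
  r <- y - design %*% b
  as.numeric(-0.5 * (sum(log(s2)) + log(det(M)) + t(r) %*% W %*% r))
}

# dense grid search for the REML tau2 over [0, 10] at the given step
oracle_reml_grid <- function(y, v, design = NULL, step = 1e-4, upper = 10) {
  if (is.null(design)) design <- matrix(1, length(y), 1)
  grid <- seq(0, upper, by = step)
  ll <- vapply(grid, oracle_reml_ll, 0, y = y, v = v, design = design)
  grid[which.max(ll)]
}

# Jeffreys-penalized logistic log-likelihood from its definition
oracle_penalized_ll <- function(X, y, beta) {
  eta <- as.numeric(X %*% beta)
  p <- 1 / (1 + exp(-eta))
  info <- t(X) %*% (X * p * (1 - p))
  d <- det(info)
  if (!is.finite(d) || d <= 0) return(-1e10)
  sum(y * eta) - sum(ifelse(eta > 0, eta + log1p(exp(-eta)),
                            log1p(exp(eta)))) +
    0.5 * log(d)
}

# refined dense grid maximization of the penalized likelihood over two
# coefficients (effective resolution ~1e-4 after refinement)
oracle_firth_grid <- function(X, y, lim = 10) {
  best <- c(0, 0)
  span <- lim
  for (round in 1:4) {
    g1 <- seq(best[1] - span, best[1] + span, length.out = 81)
    g2 <- seq(best[2] - span, best[2] + span, length.out = 81)
    ll <- outer(seq_along(g1), seq_along(g2),
                Vectorize(function(i, j)
                  oracle_penalized_ll(X, y, c(g1[i], g2[j]))))
    ix <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    best <- c(g1[ix[1]], g2[ix[2]])
    span <- span / 20
  }
  best
}

# profile of the penalized likelihood over a grid of one coefficient,
# maximizing the other by scalar search
oracle_profile_bounds <- function(X, y, j, level = 0.95,
                                  grid = seq(-30, 30, by = 0.005)) {
  other <- setdiff(1:2, j)
  prof <- vapply(grid, function(b) {
    stats::optimize(function(bo) {
      beta <- numeric(2)
      beta[j] <- b
      beta[other] <- bo
      oracle_penalized_ll(X, y, beta)
    }, c(-60, 60), maximum = TRUE, tol = 1e-9)$objective
  }, 0)
  thresh <- max(prof) - stats::qchisq(level, 1) / 2
  inside <- grid[prof >= thresh]
  c(min(inside), max(inside))
}

# small helper: one lean two-stage replicate (stage-1 + stage-2) used by
# simulation-based checks
lean_two_stage <- function(config, model = "random", tau2 = "reml") {
  mas <- gen_metaepi(config)
  s1 <- do.call(rbind, lapply(mas, stage1_delta, tau2_method = tau2))
  stage2_pool(s1, model, tau2_method = tau2)
}

# tiny trial table builder for IO and meta-epi tests
make_trial_df <- function(ma_id, sr_id, outcome_role, y, se, non_english) {
  data.frame(trial_id = paste0(ma_id, "_t", seq_along(y)), ma_id = ma_id,
             sr_id = sr_id, outcome_role = outcome_role,
             non_english = non_english, data_level = "contrast",
             arm1_mean = NA_real_, arm1_sd = NA_real_, arm1_n = NA_real_,
             arm2_mean = NA_real_, arm2_sd = NA_real_, arm2_n = NA_real_,
             smd = y, smd_se = se, stringsAsFactors = FALSE)
}

make_ma <- function(ma_id, sr_id, outcome_role, y, se, non_english) {
  ma_data(ma_id, sr_id, outcome_role,
          make_trial_df(ma_id, sr_id, outcome_role, y, se, non_english))
}
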