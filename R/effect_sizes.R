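#' Bias-corrected standardized mean difference (Hedges' g)
#'
#' Computes the standardized mean difference between two arms with the usual
#' small-sample correction, together with its large-sample sampling variance.
#' The pooled standard deviation is
#' \eqn{s_p = \sqrt{((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)}}, the
#' correction factor is \eqn{J = 1 - 3/(4(n_1+n_2-2)-1)}, and
#' \eqn{g = J\,(m_1-m_2)/s_p} with variance
#' \eqn{v = (n_1+n_2)/(n_1 n_2) + g^2/(2(n_1+n_2))}.
#'
#' The sign convention is arm 1 minus arm 2; callers must keep arm ordering
#' consistent across the trials of one meta-analysis.
#'
#' @param m1,m2 arm means (outcome units).
#' @param s1,s2 arm standard deviations; must be non-negative and not both 0.
#' @param n1,n2 arm sample sizes, at least 2 each.
#' @param correct apply the small-sample correction (Hedges' g). With
#'   `FALSE` the plain Cohen's d is returned, for sensitivity analyses.
#' @return A list with components `y` (the effect estimate, unitless) and
#'   `v` (its sampling variance). All arguments are vectorized.
#' @examples
#' hedges_g(10, 2, 20, 8, 2, 20)
#' @export
hedges_g <- function(m1, s1, n1, m2, s2, n2, correct = TRUE) {
  if (any(n1 < 2) || any(n2 < 2)) {
    stop("each arm needs at least 2 observations")
  }
  if (any(s1 < 0) || any(s2 < 0)) {
    stop("arm standard deviations must be non-negative")
  }
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df)
  if (any(sp == 0)) {
    stop("degenerate pooled standard deviation (both arm SDs are zero)")
  }
  j <- if (correct) 1 - 3 / (4 * df - 1) else rep(1, length(df))
  g <- j * (m1 - m2) / sp
  n <- n1 + n2
  v <- n / (n1 * n2) + g^2 / (2 * n)
  list(y = g, v = v)
}

#' Effect estimate for a single trial record
#'
#' Arm-level records are converted with [hedges_g()]; contrast-level records
#' pass through as `y = smd`, `v = smd_se^2`.
#'
#' @param trial a one-row data frame (or list) with the trial-record fields
#'   (`data_level`, the `arm1_*`/`arm2_*` block or the `smd`/`smd_se` block).
#' @param correct passed to [hedges_g()] for arm-level records.
#' @return list with `y` and `v`.
#' @export
to_effect <- function(trial, correct = TRUE) {
  if (identical(as.character(trial$data_level), "arm")) {
    hedges_g(trial$arm1_mean, trial$arm1_sd, trial$arm1_n,
             trial$arm2_mean, trial$arm2_sd, trial$arm2_n,
             correct = correct)
  } else {
    list(y = as.numeric(trial$smd), v = as.numeric(trial$smd_se)^2)
  }
}

#' Effect estimates for a table of trials
#'
#' Vectorized [to_effect()] over the rows of a trial table; arm- and
#' contrast-level rows may be mixed.
#'
#' @param trials a trial-record data frame.
#' @param correct passed to [hedges_g()].
#' @return data frame with columns `y` and `v`, one row per trial, in input
#'   order.
#' @export
trial_effects <- function(trials, correct = TRUE) {
  y <- numeric(nrow(trials))
  v <- numeric(nrow(trials))
  arm <- trials$data_level == "arm"
  if (any(arm)) {
    e <- hedges_g(trials$arm1_mean[arm], trials$arm1_sd[arm],
                  trials$arm1_n[arm], trials$arm2_mean[arm],
                  trials$arm2_sd[arm], trials$arm2_n[arm], correct = correct)
    y[arm] <- e$y
    v[arm] <- e$v
  }
  if (any(!arm)) {
    y[!arm] <- trials$smd[!arm]
    v[!arm] <- trials$smd_se[!arm]^2
  }
  data.frame(y = y, v = v)
}
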