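# Two-stage meta-epidemiological estimation of language bias.
#
# Stage 1: within each eligible meta-analysis, a random-effects
# meta-regression of trial effect estimates on the non-English indicator
# estimates dSMD, the difference in standardized mean difference between
# non-English and English trials. Stage 2: the per-meta-analysis dSMDs are
# pooled across meta-analyses under a random-effects model (between-MA
# variance kappa^2), with a fixed-effect sensitivity analysis.

#' Construct a meta-analysis data object
#'
#' @param ma_id,sr_id identifiers of the meta-analysis and its parent
#'   systematic review.
#' @param outcome_role `"primary"` or `"secondary"`.
#' @param trials trial-record data frame (see [read_trial_table()] for the
#'   column contract); file/input order is preserved.
#' @return object of class `ma_data`.
#' @export
ma_data <- function(ma_id, sr_id, outcome_role, trials) {
  outcome_role <- match.arg(outcome_role, c("primary", "secondary"))
  trials <- validate_trials(trials, ma_id)
  structure(list(ma_id = as.character(ma_id), sr_id = as.character(sr_id),
                 outcome_role = outcome_role, trials = trials),
            class = "ma_data")
}

#' @export
print.ma_data <- function(x, ...) {
  cat(sprintf("meta-analysis %s (SR %s, %s outcome): %d trials, %d non-English\n",
              x$ma_id, x$sr_id, x$outcome_role, nrow(x$trials),
              sum(x$trials$non_english)))
  invisible(x)
}

#' Select the eligible meta-analysis of a systematic review
#'
#' Applies the selection algorithm: the first primary-outcome meta-analysis
#' with at least three trials of which at least one is non-English; if no
#' primary-outcome meta-analysis qualifies, the first qualifying
#' secondary-outcome one; otherwise none.
#'
#' @param mas list of [ma_data()] objects in the order reported by the
#'   review.
#' @return an `ma_data` object, or `NULL` when no meta-analysis qualifies.
#' @export
select_meta_analysis <- function(mas) {
  eligible <- function(ma) {
    nrow(ma$trials) >= 3 && sum(ma$trials$non_english) >= 1
  }
  for (role in c("primary", "secondary")) {
    for (ma in mas) {
      if (ma$outcome_role == role && eligible(ma)) return(ma)
    }
  }
  NULL
}

#' Stage-1 language-bias estimate for one meta-analysis
#'
#' Converts trials to effect estimates ([trial_effects()]) and regresses them
#' on the non-English indicator (coded non-English = 1) via random-effects
#' meta-regression. The moderator coefficient is dSMD; a negative dSMD means
#' non-English trials yield a larger effect in the direction reported (they
#' overestimate the SMD).
#'
#' @param ma an [ma_data()] object satisfying the eligibility rule.
#' @param tau2_method between-trial variance estimator, `"reml"` or `"dl"`.
#' @param correct small-sample correction for arm-level records.
#' @return one-row data frame with `ma_id`, `sr_id`, `delta`, `var_delta`,
#'   `tau2`, `k_total`, `k_nonenglish`.
#' @export
stage1_delta <- function(ma, tau2_method = c("reml", "dl"), correct = TRUE) {
  tau2_method <- match.arg(tau2_method)
  eff <- trial_effects(ma$trials, correct = correct)
  fit <- meta_regress(eff$y, eff$v, as.numeric(ma$trials$non_english),
                      tau2_method = tau2_method)
  data.frame(ma_id = ma$ma_id, sr_id = ma$sr_id,
             delta = unname(fit$coef["moderator"]),
             var_delta = fit$cov["moderator", "moderator"],
             tau2 = fit$tau2, k_total = nrow(ma$trials),
             k_nonenglish = sum(ma$trials$non_english))
}

#' Stage-2 pooling of per-meta-analysis bias estimates
#'
#' Treats each (dSMD, variance) pair as an effect estimate and pools across
#' meta-analyses. The random model estimates the between-meta-analysis
#' variance kappa^2 of the dSMDs; the fixed model sets it to zero (the
#' sensitivity analysis). At most one meta-analysis per systematic review is
#' allowed, to avoid correlated contributions.
#'
#' @param deltas data frame of stage-1 estimates (from [stage1_delta()]).
#' @param model `"random"` or `"fixed"`.
#' @param tau2_method kappa^2 estimator for the random model.
#' @return object of class `bias_summary`: `model`, `pooled_delta`,
#'   `ci_low`, `ci_high`, `p_value`, `kappa2`, `n_ma`.
#' @export
stage2_pool <- function(deltas, model = c("random", "fixed"),
                        tau2_method = c("reml", "dl")) {
  model <- match.arg(model)
  tau2_method <- match.arg(tau2_method)
  if (nrow(deltas) < 2) stop("need at least 2 meta-analyses to pool")
  if (anyDuplicated(deltas$sr_id)) {
    stop("more than one meta-analysis from the same systematic review: ",
         paste(unique(deltas$sr_id[duplicated(deltas$sr_id)]), collapse = ", "))
  }
  pe <- if (model == "random") {
    pool_random(deltas$delta, deltas$var_delta, tau2_method)
  } else {
    pool_fixed(deltas$delta, deltas$var_delta)
  }
  structure(list(model = model, pooled_delta = pe$mu, se = pe$se,
                 ci_low = pe$ci_low, ci_high = pe$ci_high,
                 p_value = pe$p_value, kappa2 = pe$het$tau2,
                 n_ma = nrow(deltas), het = pe$het),
            class = "bias_summary")
}

#' @export
print.bias_summary <- function(x, ...) {
  cat(sprintf("%s-effect%s pooled dSMD over %d meta-analyses: %.3f (95%% CI %.3f to %.3f), p = %.3f\n",
              if (x$model == "fixed") "fixed" else "random",
              if (x$model == "fixed") "" else "s",
              x$n_ma, x$pooled_delta, x$ci_low, x$ci_high, x$p_value))
  if (x$model == "random") {
    cat(sprintf("between-meta-analysis variance kappa2 = %.4f\n", x$kappa2))
  }
  invisible(x)
}

#' Language-subset sensitivity analysis for one meta-analysis
#'
#' Pools the trial effects of one meta-analysis twice: over all trials and
#' over the English-only subset, to show how inclusion of non-English trials
#' changes the summary SMD and the between-study heterogeneity.
#'
#' @inheritParams stage1_delta
#' @return list with `all` (a `pooled_estimate`) and `english_only` (a
#'   `pooled_estimate`, or `NULL` with `english_only_available = FALSE` when
#'   fewer than two English trials remain).
#' @export
language_subset_sensitivity <- function(ma, tau2_method = c("reml", "dl"),
                                        correct = TRUE) {
  tau2_method <- match.arg(tau2_method)
  eff <- trial_effects(ma$trials, correct = correct)
  all_pool <- pool_random(eff$y, eff$v, tau2_method)
  en <- !ma$trials$non_english
  if (sum(en) >= 2) {
    list(ma_id = ma$ma_id, all = all_pool,
         english_only = pool_random(eff$y[en], eff$v[en], tau2_method),
         english_only_available = TRUE)
  } else {
    list(ma_id = ma$ma_id, all = all_pool, english_only = NULL,
         english_only_available = FALSE)
  }
}

#' Fit the two-stage language-bias model
#'
#' The main fitting function. From a collection of meta-analyses (typically
#' one systematic review contributes several candidate meta-analyses), it
#' (i) selects at most one eligible meta-analysis per systematic review with
#' [select_meta_analysis()], (ii) estimates dSMD within each selected
#' meta-analysis ([stage1_delta()]), and (iii) pools the dSMDs across
#' meta-analyses under both random- and fixed-effect models
#' ([stage2_pool()]), together with per-meta-analysis language-subset
#' sensitivity summaries.
#'
#' @param mas list of [ma_data()] objects (e.g. from [read_trial_table()] or
#'   [gen_metaepi()]), in reported order.
#' @param tau2_method heterogeneity estimator for both stages, `"reml"`
#'   (default) or `"dl"`.
#' @param correct small-sample correction for arm-level effect sizes.
#' @param subset_sensitivity also compute [language_subset_sensitivity()]
#'   per selected meta-analysis.
#' @return object of class `langbias` with components `stage1` (data frame,
#'   one row per selected meta-analysis), `random` and `fixed`
#'   (`bias_summary` objects), `sensitivity`, `n_sr`, `n_selected`,
#'   `tau2_method`. Supported methods: `print`, `summary`, `coef`,
#'   `confint`, `plot`.
#' @examples
#' mas <- gen_metaepi(metaepi_config(K = 20, seed = 7))
#' fit <- langbias(mas)
#' fit
#' coef(fit)
#' confint(fit)
#' @export
langbias <- function(mas, tau2_method = c("reml", "dl"), correct = TRUE,
                     subset_sensitivity = TRUE) {
  tau2_method <- match.arg(tau2_method)
  if (inherits(mas, "ma_data")) mas <- list(mas)
  stopifnot(length(mas) >= 1, all(vapply(mas, inherits, TRUE, "ma_data")))
  sr_ids <- vapply(mas, `[[`, "", "sr_id")
  selected <- list()
  for (sr in unique(sr_ids)) {
    ma <- select_meta_analysis(mas[sr_ids == sr])
    if (!is.null(ma)) selected[[length(selected) + 1L]] <- ma
  }
  if (length(selected) < 2) {
    stop("fewer than 2 systematic reviews contribute an eligible meta-analysis")
  }
  stage1 <- do.call(rbind, lapply(selected, stage1_delta,
                                  tau2_method = tau2_method,
                                  correct = correct))
  sens <- if (subset_sensitivity) {
    lapply(selected, language_subset_sensitivity, tau2_method = tau2_method,
           correct = correct)
  }
  structure(
    list(stage1 = stage1,
         random = stage2_pool(stage1, "random", tau2_method),
         fixed = stage2_pool(stage1, "fixed"),
         sensitivity = sens,
         n_sr = length(unique(sr_ids)), n_selected = length(selected),
         tau2_method = tau2_method),
    class = "langbias")
}

#' @export
print.langbias <- function(x, ...) {
  cat("Two-stage language-bias analysis\n")
  cat(sprintf("%d systematic reviews, %d eligible meta-analyses (tau2: %s)\n\n",
              x$n_sr, x$n_selected, x$tau2_method))
  print(x$random)
  print(x$fixed)
  cat("\nNegative dSMD: non-English trials overestimate the SMD.\n")
  invisible(x)
}

#' @export
summary.langbias <- function(object, ...) {
  structure(list(fit = object), class = "summary.langbias")
}

#' @export
print.summary.langbias <- function(x, ...) {
  print(x$fit)
  cat("\nPer-meta-analysis estimates (stage 1):\n")
  s1 <- x$fit$stage1
  s1$ci_low <- s1$delta - stats::qnorm(0.975) * sqrt(s1$var_delta)
  s1$ci_high <- s1$delta + stats::qnorm(0.975) * sqrt(s1$var_delta)
  print(s1, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
coef.langbias <- function(object, ...) {
  c(random = object$random$pooled_delta, fixed = object$fixed$pooled_delta)
}

#' @export
confint.langbias <- function(object, parm, level = 0.95, ...) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  m <- rbind(
    random = c(object$random$pooled_delta - zq * object$random$se,
               object$random$pooled_delta + zq * object$random$se),
    fixed = c(object$fixed$pooled_delta - zq * object$fixed$se,
              object$fixed$pooled_delta + zq * object$fixed$se))
  colnames(m) <- sprintf("%g %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  m
}

#' Forest plot of per-meta-analysis language-bias estimates
#'
#' @param x a `langbias` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.langbias <- function(x, ...) {
  s1 <- x$stage1
  zq <- stats::qnorm(0.975)
  lo <- s1$delta - zq * sqrt(s1$var_delta)
  hi <- s1$delta + zq * sqrt(s1$var_delta)
  n <- nrow(s1)
  ys <- rev(seq_len(n) + 1)
  graphics::plot(NA, xlim = range(lo, hi, 0, x$random$ci_low, x$random$ci_high),
                 ylim = c(0.5, n + 1.5), yaxt = "n",
                 xlab = expression(Delta * "SMD (non-English - English)"),
                 ylab = "", ...)
  graphics::axis(2, at = c(ys, 1), labels = c(s1$ma_id, "pooled (random)"),
                 las = 1, cex.axis = 0.7)
  graphics::segments(lo, ys, hi, ys)
  graphics::points(s1$delta, ys, pch = 15)
  graphics::segments(x$random$ci_low, 1, x$random$ci_high, 1, lwd = 2)
  graphics::points(x$random$pooled_delta, 1, pch = 18, cex = 1.4)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}
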