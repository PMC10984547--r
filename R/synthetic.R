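# Synthetic-data generators. The extracted datasets behind the
# meta-epidemiological analysis are not publicly deposited, so these
# generators emulate their statistical structure: trials nested in
# meta-analyses with a per-meta-analysis language-bias effect, and a
# review-characteristics table drawn from a logistic model (optionally with
# complete separation, to exercise the Firth fit).

#' Configuration of the meta-epidemiological trial generator
#'
#' Defaults encode the study conditions the analysis assumes: per-MA true
#' effects theta_k ~ N(`mu_theta`, `sd_theta`^2); per-MA language-bias
#' effects b_k ~ N(`delta`, `kappa`^2); within-MA heterogeneity SD `tau`;
#' trial true effect theta_k + b_k L_i + N(0, tau^2) where L_i indicates a
#' non-English trial; two normal arms with common SD `sigma` and mean
#' difference equal to the true effect times `sigma`, so the true SMD equals
#' the true effect.
#'
#' @param K number of meta-analyses.
#' @param k_range min/max trials per meta-analysis.
#' @param p_ne probability a trial is non-English (at least one forced per
#'   meta-analysis by resampling the language labels).
#' @param mu_theta,sd_theta mean and SD of per-MA true effects.
#' @param tau within-MA heterogeneity SD.
#' @param delta mean language-bias effect (negative: non-English trials
#'   overestimate the SMD).
#' @param kappa SD of the per-MA bias effects.
#' @param n_range min/max per-arm sample size.
#' @param sigma common outcome SD.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return list of class `metaepi_config`.
#' @export
metaepi_config <- function(K, k_range = c(3, 12), p_ne = 0.25,
                           mu_theta = 0.3, sd_theta = 0.3, tau = 0.3,
                           delta = -0.3, kappa = 0.1, n_range = c(15, 60),
                           sigma = 1, seed = NULL) {
  stopifnot(K >= 1, length(k_range) == 2, k_range[1] >= 3,
            k_range[1] <= k_range[2], p_ne > 0, p_ne < 1, sd_theta >= 0,
            tau >= 0, kappa >= 0, length(n_range) == 2, n_range[1] >= 2,
            n_range[1] <= n_range[2], sigma > 0)
  structure(list(K = K, k_range = k_range, p_ne = p_ne, mu_theta = mu_theta,
                 sd_theta = sd_theta, tau = tau, delta = delta,
                 kappa = kappa, n_range = n_range, sigma = sigma,
                 seed = seed),
            class = "metaepi_config")
}

#' Generate meta-epidemiological trial data
#'
#' Draws `K` meta-analyses under the model described in
#' [metaepi_config()]. Arm summary statistics are drawn from their exact
#' sampling distributions under normally distributed outcomes: the arm mean
#' from N(true mean, sigma^2/n) and the arm SD from the scaled-chi
#' distribution sigma * sqrt(chisq(n-1)/(n-1)).
#'
#' @param config a [metaepi_config()].
#' @return list of [ma_data()] objects, one per meta-analysis (each assigned
#'   to its own systematic review, primary outcome).
#' @examples
#' mas <- gen_metaepi(metaepi_config(K = 5, seed = 1))
#' @export
gen_metaepi <- function(config) {
  stopifnot(inherits(config, "metaepi_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  K <- config$K
  rint <- function(n, lo, hi) lo + sample.int(hi - lo + 1, n, replace = TRUE) - 1L
  k_i <- rint(K, config$k_range[1], config$k_range[2])
  theta <- stats::rnorm(K, config$mu_theta, config$sd_theta)
  b <- stats::rnorm(K, config$delta, config$kappa)
  n_tot <- sum(k_i)
  ma_of <- rep(seq_len(K), k_i)
  lang <- stats::rbinom(n_tot, 1, config$p_ne)
  # force at least one non-English and one English trial per MA by
  # resampling labels (keeps them exchangeable within the MA); a
  # single-language meta-analysis carries no within-MA language contrast
  repeat {
    ne_per_ma <- tapply(lang, ma_of, sum)
    bad <- which(ne_per_ma == 0 | ne_per_ma == k_i)
    if (!length(bad)) break
    idx <- ma_of %in% bad
    lang[idx] <- stats::rbinom(sum(idx), 1, config$p_ne)
  }
  d <- theta[ma_of] + b[ma_of] * lang + stats::rnorm(n_tot, 0, config$tau)
  n1 <- rint(n_tot, config$n_range[1], config$n_range[2])
  n2 <- rint(n_tot, config$n_range[1], config$n_range[2])
  s <- config$sigma
  m1 <- stats::rnorm(n_tot, d * s, s / sqrt(n1))
  m2 <- stats::rnorm(n_tot, 0, s / sqrt(n2))
  s1 <- s * sqrt(stats::rchisq(n_tot, n1 - 1) / (n1 - 1))
  s2 <- s * sqrt(stats::rchisq(n_tot, n2 - 1) / (n2 - 1))
  fmt <- paste0("%0", nchar(K), "d")
  trials <- data.frame(
    trial_id = sprintf("t%s_%02d", sprintf(fmt, ma_of),
                       unlist(lapply(k_i, seq_len))),
    ma_id = sprintf(paste0("ma", fmt), ma_of),
    sr_id = sprintf(paste0("sr", fmt), ma_of),
    outcome_role = "primary",
    non_english = lang == 1,
    data_level = "arm",
    arm1_mean = m1, arm1_sd = s1, arm1_n = n1,
    arm2_mean = m2, arm2_sd = s2, arm2_n = n2,
    smd = NA_real_, smd_se = NA_real_,
    stringsAsFactors = FALSE)
  lapply(split(trials, trials$ma_id)[unique(trials$ma_id)], function(tr) {
    ma_data(tr$ma_id[1], tr$sr_id[1], "primary", tr)
  })
}

# default marginals: overall relative frequencies of the motivating survey
# of 174 orthodontic systematic reviews (2017-2021)
default_sr_marginals <- function() {
  list(
    n_authors_band = c("1-3" = 43, "4-6" = 111, "7-9" = 20) / 174,
    continent = c(America = 46, AsiaOther = 51, Europe = 77) / 174,
    cochrane = c(yes = 9, no = 165) / 174,
    year = c("2017" = 28, "2018" = 32, "2019" = 29, "2020" = 37,
             "2021" = 48) / 174,
    prospero = c(no = 49, yes = 125) / 174,
    language_restriction = c(no = 135, yes = 33) / 168,
    excluded_nonenglish = c(no = 170, yes = 4) / 174,
    librarian = c(no = 137, yes = 37) / 174,
    ma_performed = c(no = 77, yes = 97) / 174,
    sr_type = c(diagnostic = 9, epidemiological = 19,
                interventional = 146) / 174,
    study_type = c(animal = 12, human = 159, invitro = 3) / 174)
}

#' Configuration of the review-characteristics generator
#'
#' @param N number of systematic reviews.
#' @param marginals named list of per-field category probabilities;
#'   defaults to the marginal relative frequencies of the motivating survey.
#' @param beta named log-odds coefficients of the logistic model for
#'   including non-English studies, on the columns of
#'   [prepare_covariates()]; unnamed columns get 0. Default: intercept at
#'   the observed inclusion rate (45/174), all slopes 0.
#' @param force_separation make one covariate level (explicit exclusion of
#'   non-English studies) perfectly predict the response, to exercise the
#'   Firth fit.
#' @param seed integer seed.
#' @return list of class `sr_config`.
#' @export
sr_config <- function(N = 174, marginals = default_sr_marginals(),
                      beta = c(intercept = stats::qlogis(45 / 174)),
                      force_separation = FALSE, seed = NULL) {
  stopifnot(N >= 1)
  for (f in names(marginals)) {
    if (abs(sum(marginals[[f]]) - 1) > 1e-8) {
      stop("marginal probabilities for ", f, " must sum to 1")
    }
  }
  structure(list(N = N, marginals = marginals, beta = beta,
                 force_separation = force_separation, seed = seed),
            class = "sr_config")
}

#' Generate a review-characteristics table
#'
#' Covariates are drawn independently from the configured marginals,
#' `n_included` from a discretized lognormal (clamped to \[2, 94\]) and
#' search precision from a lognormal (clamped to \[0.001, 0.27\]); the
#' response (inclusion of non-English studies) follows the configured
#' logistic model. With `force_separation`, reviews that explicitly
#' excluded non-English studies never include one.
#'
#' @param config an [sr_config()].
#' @return validated review-characteristics data frame (as from
#'   [read_sr_table()]).
#' @export
gen_sr_table <- function(config) {
  stopifnot(inherits(config, "sr_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  N <- config$N
  m <- config$marginals
  draw <- function(f) {
    sample(names(m[[f]]), N, replace = TRUE, prob = m[[f]])
  }
  rec <- data.frame(
    sr_id = sprintf("sr%03d", seq_len(N)),
    n_authors_band = draw("n_authors_band"),
    continent = draw("continent"),
    cochrane = draw("cochrane") == "yes",
    year = as.integer(draw("year")),
    prospero = draw("prospero") == "yes",
    n_included = pmin(pmax(round(stats::rlnorm(N, log(11), 0.65)), 2), 94),
    language_restriction = draw("language_restriction") == "yes",
    excluded_nonenglish = draw("excluded_nonenglish") == "yes",
    librarian = draw("librarian") == "yes",
    ma_performed = draw("ma_performed") == "yes",
    sr_type = draw("sr_type"),
    study_type = draw("study_type"),
    stringsAsFactors = FALSE)
  prec <- pmin(pmax(stats::rlnorm(N, log(0.02), 0.9), 0.001), 0.27)
  rec$n_retrieved <- pmax(round(rec$n_included / prec), rec$n_included)
  # response from the logistic model on the prepared covariates
  tmp <- rec
  tmp$non_english_included <- FALSE
  tmp$n_nonenglish_langs <- NA_integer_
  pc <- prepare_covariates(tmp)
  beta <- numeric(ncol(pc$X))
  names(beta) <- colnames(pc$X)
  common <- intersect(names(config$beta), names(beta))
  beta[common] <- config$beta[common]
  eta <- drop(pc$X %*% beta)
  y <- stats::rbinom(N, 1, stats::plogis(eta)) == 1
  if (config$force_separation) y[rec$excluded_nonenglish] <- FALSE
  rec$non_english_included <- y
  rec$n_nonenglish_langs <- ifelse(y, 1L + stats::rpois(N, 1), NA_integer_)
  validate_sr(rec)
}
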