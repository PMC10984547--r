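---
title: "Estimating language bias in systematic reviews: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating language bias in systematic reviews: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(langbias)
```

## The scientific problem

Systematic reviews that restrict their searches or eligibility criteria to
English-language trials risk *language bias*: if statistically significant
findings are preferentially published in English, an English-only evidence
base can misestimate treatment effects. `langbias` implements a
meta-epidemiological analysis of this question, treating meta-analyses as
the units of analysis and publication language as the trial-level exposure
of interest, together with a penalized logistic regression associating
review-level characteristics with the inclusion of non-English studies.

## The two-stage model

**Effect measure.** Trials contribute standardized mean differences. For
arm-level data (means $m_1, m_2$, SDs $s_1, s_2$, sizes $n_1, n_2$) we use
Hedges' $g$:

$$
g = J\,\frac{m_1 - m_2}{s_p},\qquad
s_p = \sqrt{\tfrac{(n_1-1)s_1^2 + (n_2-1)s_2^2}{n_1+n_2-2}},\qquad
J = 1 - \tfrac{3}{4(n_1+n_2-2)-1},
$$

with sampling variance $v = \frac{n_1+n_2}{n_1 n_2} + \frac{g^2}{2(n_1+n_2)}$.
Which SMD flavour underlies a published forest plot is generally
unknowable per review, so the small-sample correction can be switched off
(`correct = FALSE`, giving Cohen's $d$) as a sensitivity analysis.
Contrast-level rows (an SMD with its standard error, as read off a forest
plot) are taken verbatim. Signs are taken as reported within each
meta-analysis; no attempt is made to harmonize outcome direction *across*
meta-analyses, because the stage-1 statistic is a within-meta-analysis
contrast and the bias estimates are pooled as extracted.

**Eligibility and selection.** One meta-analysis is selected per
systematic review: the first primary-outcome meta-analysis with at least
three trials including at least one non-English trial; failing that, the
first such secondary-outcome meta-analysis; failing that, none. A trial
counts once regardless of how many comparisons it contributes. Selecting
at most one meta-analysis per review avoids correlated contributions in
stage 2, and the fit refuses to pool two estimates sharing a review
identifier.

**Stage 1 (within meta-analysis).** For meta-analysis $k$ with trial
effects $y_{ki}$, variances $v_{ki}$ and non-English indicators $L_{ki}$,
a random-effects meta-regression

$$
y_{ki} = \beta_{0k} + \Delta_k L_{ki} + u_{ki} + e_{ki},
\qquad u_{ki} \sim N(0, \tau_k^2),\; e_{ki} \sim N(0, v_{ki})
$$

is fitted by weighted least squares with weights $1/(v_{ki} +
\hat\tau_k^2)$. The moderator coefficient $\hat\Delta_k$ is the
difference in SMD between non-English and English trials (dSMD); a
negative value means non-English trials push the summary effect further in
the reported direction, i.e. they overestimate the SMD.

**Stage 2 (across meta-analyses).** The pairs $(\hat\Delta_k,
\widehat{\mathrm{var}}(\hat\Delta_k))$ are pooled by inverse-variance
meta-analysis. The random-effects model estimates the between-meta-analysis
variance $\kappa^2$ of the bias effects; a fixed-effect pooling ($\kappa^2
= 0$) is reported as a sensitivity analysis. Confidence intervals use
normal quantiles throughout, matching the conventional output of standard
meta-analysis software; the Knapp–Hartung adjustment is deliberately not
applied by default since the analysis this package models did not use it.

**Heterogeneity estimation.** $\tau^2$ (and $\kappa^2$) default to REML —
the default of the multilevel meta-regression function the analysis this
package models was run with — maximized by bounded scalar search on
$[0, 100]$ with tolerance $10^{-8}$ (deterministic, no starting-value
sensitivity). DerSimonian–Laird moment estimation is available as an
option (`tau2_method = "dl"`); for regression designs the moment estimator
generalizes to $\hat\tau^2 = \max(0, (Q_E - (k-p))/\mathrm{tr}(P))$, which
reduces to the usual DL formula for the intercept-only design. Estimates
are truncated at zero. The degenerate all-identical case is guarded:
$Q = 0$ yields $I^2 = 0$ by convention. Only a single additive
between-trial variance component is implemented; richer multilevel
structures (e.g. effects nested in multi-arm trials) are out of scope, and
each trial is assumed to contribute one effect row.

## The association model

Whether a review includes non-English studies is modelled by multivariable
binary logistic regression on the review characteristics (author-count
band, continent, Cochrane status, centred publication year, registration,
number of included studies, logit search precision, language restriction,
explicit exclusion of non-English studies, librarian involvement,
meta-analysis conduct, review type, study type), all entered
simultaneously with no variable selection. Several characteristics exhibit
(quasi-)separation — e.g. no review that explicitly excluded non-English
studies ever includes one — under which maximum-likelihood estimates are
non-finite. We therefore fit by Firth's bias-reduced likelihood

$$
l^*(\beta) = l(\beta) + \tfrac12 \log\det I(\beta),
$$

via modified Fisher scoring with hat-value-adjusted responses
(per-observation adjustment $h_i(\tfrac12 - \pi_i)$), step-halving when the
penalized likelihood would decrease, and convergence declared at max
$|U^*| < 10^{-6}$ with step norm $< 10^{-8}$ (cap 100 iterations).
Confidence intervals are profile penalized-likelihood intervals (bisection
to $10^{-6}$; a bound is declared infinite only if the profile stays above
the $\chi^2_1$ threshold out to $\pm 50$ log-odds) and p-values are
penalized likelihood-ratio tests, so $p < 0.05$ coincides exactly with the
95% interval excluding the null. In the deep tails the scoring step can
become numerically unstable (fitted probabilities collapse to 0/1); the
profile evaluation then falls back to direct quasi-Newton maximization of
the penalized likelihood. Reference levels for dummy coding follow the
summary-table convention (band 1–3, America, Cochrane, no registration, no
restriction, no exclusion, no librarian, no meta-analysis, diagnostic,
animal). Search precision (included/retrieved, in $(0,1]$) enters on the
logit scale, with exact 1.0 clamped to $1-10^{-6}$ under a warning;
publication year is centred on its sample mean. Rows missing a model
covariate are dropped from the regression (complete case) but retained in
descriptives, whose percentages are computed over non-missing values.
Quartiles use the type-7 (linear interpolation) rule so interquartile
ranges are deterministic and reproducible.

The univariate 2×2 analysis (statistical significance against non-English
inclusion) uses the saturated-model identity: the logistic slope equals
the log cross-product ratio exactly, so `fit_mle_2x2()` computes it in
closed form with Wald inference.

## The synthetic-data generators

The extracted datasets behind the motivating survey were not deposited, so
the package generates data with the statistical structure the analysis
assumes.

**Trial generator** (`gen_metaepi()`). For meta-analysis $k$: a true
effect $\theta_k \sim N(\mu_\theta, \sigma_\theta^2)$ and a language-bias
effect $b_k \sim N(\delta, \kappa^2)$; trial $i$ has true effect $\theta_k
+ b_k L_{ki} + N(0, \tau^2)$ and two normal arms with common SD $\sigma$
whose mean difference is the true effect times $\sigma$, so the true SMD
equals the true effect. Arm summary statistics are drawn from their exact
sampling distributions (mean $\sim N(\cdot, \sigma^2/n)$, SD
$\sim \sigma\sqrt{\chi^2_{n-1}/(n-1)}$), which is distributionally
identical to simulating raw outcomes and fully vectorized. Defaults encode
the study conditions the package is calibrated under: $\delta = -0.3$ (the
magnitude of overestimation the motivating survey reported),
$\kappa = 0.1$, $\tau = 0.3$ (substantial within-meta-analysis
heterogeneity), $\mu_\theta = 0.3$, $\sigma_\theta = 0.3$, 3–12 trials per
meta-analysis, non-English probability 0.25, per-arm sizes 15–60. Language
labels are resampled wholesale until each meta-analysis has at least one
trial of each language, keeping labels exchangeable within a
meta-analysis; a single-language meta-analysis is excluded because it
carries no within-meta-analysis language contrast. The generator does
*not* emulate publication-bias or small-study-effect mechanisms, risk-of-
bias differences between languages, correlated multi-arm trials, or
non-normal outcomes — so passing calibration checks demonstrate correctness
of the estimator under its own model, not robustness to those phenomena.

**Review-table generator** (`gen_sr_table()`). Characteristics are drawn
independently from configurable marginals (defaulting to the motivating
survey's relative frequencies) and the response from a logistic model on
the prepared design; `force_separation` makes explicit exclusion of
non-English studies perfectly predict the response, exercising the Firth
machinery.

**Deterministic fixture** (`sr_fixture()`). A fixed 174-row table whose
per-field counts — overall and by non-English inclusion — equal every
published count, including footnoted missingness, 2568 included studies of
which 98 non-English, and the published metric summaries under the type-7
quartile rule. Two published values cannot be reproduced jointly and are
resolved as follows: (i) the third quartile 16.50 printed for included
studies in the non-inclusive subgroup is not attainable by any integer
sample of 129 under type-7 quantiles (position 97 is an exact order
statistic), indicating a different quantile convention at the source; the
fixture's value is 16. (ii) The published share of non-English studies
(3.78%) disagrees with the published fraction it annotates (98/2568 =
3.82%); the fixture reproduces the counts, and the share it yields is the
one the counts imply. The fixture's joint structure across fields is an
arbitrary deterministic layout (modular permutations decorrelate the
fields and keep the design full rank); it is synthetic and must not be
mistaken for the survey's row-level data.

## Numerical and design choices

- dSMD sign convention: moderator coded non-English = 1, effects taken as
  reported, so negative pooled dSMD means non-English trials overestimate.
- Eligibility counts trials, not comparison rows (conservative reading).
- Contrast-level SMDs are accepted verbatim; how the original reviews
  standardized them is unknowable from a forest plot.
- REML optimizer bounds $[0, 100]$ in SMD$^2$ units, far above any
  plausible between-study variance for standardized effects.
- The CSV dialect is comma-separated UTF-8 with a mandatory header;
  booleans are written yes/no and missing values as empty fields, matching
  extraction-spreadsheet conventions; within-file trial order is preserved
  end to end so forest plots keep the reported ordering.
- Calibration problem sizes, chosen as the package's standing simulation
  conditions: recovery uses $K = 200$ meta-analyses and 500 replicates for
  interval coverage; null calibration ($\delta = 0$, $\kappa = 0$) uses
  1000 replicates of $K = 14$ meta-analyses, matching the scale of the
  motivating dataset.

## A worked example

```{r example}
mas <- gen_metaepi(metaepi_config(K = 14, seed = 7))
fit <- langbias(mas)
fit
confint(fit)
```

```{r forest, fig.width = 6, fig.height = 4}
plot(fit)
```

The association analysis on the packaged fixture:

```{r assoc}
sr <- sr_fixture()
pc <- prepare_covariates(sr)
d <- as.data.frame(pc$X[, -1])
d$y <- pc$y
assoc <- firth_logistic(y ~ restriction + librarian + ma_performed, d)
assoc
```

## Known limitations

- Stage 1 treats the per-meta-analysis variance estimates
  $\widehat{\mathrm{var}}(\hat\Delta_k)$ as known in stage 2. With only a
  handful of trials per meta-analysis these estimates are noisy, and
  inverse-variance weighting rewards meta-analyses whose heterogeneity is
  underestimated; the stage-2 fixed-effect z-test therefore runs
  anti-conservative under realistic within-meta-analysis heterogeneity.
  This is a property of the conventional two-stage pipeline itself — and
  the reason its fixed-effect result should be read as a sensitivity
  analysis, not the primary inference.
- Profile intervals for very large models can be slow (each coefficient
  requires repeated constrained refits).
- The generators draw covariates independently; real review
  characteristics are correlated.
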