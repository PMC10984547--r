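test_that("meta-analysis selection follows the eligibility algorithm", {
  p3 <- make_ma("m1", "s1", "primary", c(0.1, 0.2, 0.3), rep(0.1, 3),
                c(FALSE, FALSE, TRUE))
  p2 <- make_ma("m2", "s1", "primary", c(0.1, 0.2), rep(0.1, 2),
                c(FALSE, TRUE))
  sec <- make_ma("m3", "s1", "secondary", c(0.1, 0.2, 0.3, 0.4), rep(0.1, 4),
                 c(FALSE, TRUE, FALSE, FALSE))
  all_en <- make_ma("m4", "s1", "primary", c(0.1, 0.2, 0.3, 0.4, 0.5),
                    rep(0.1, 5), rep(FALSE, 5))

  expect_identical(select_meta_analysis(list(p3))$ma_id, "m1")
  # primary too small: fall through to the first eligible secondary
  expect_identical(select_meta_analysis(list(p2, sec))$ma_id, "m3")
  # eligible primary preferred over an earlier-listed secondary
  expect_identical(select_meta_analysis(list(sec, p3))$ma_id, "m1")
  expect_null(select_meta_analysis(list(all_en)))
  expect_null(select_meta_analysis(list(p2)))
})

test_that("stage-1 dSMD is the saturated group-mean difference", {
  ma <- make_ma("m1", "s1", "primary", c(0, 0, -0.4), rep(0.1, 3),
                c(FALSE, FALSE, TRUE))
  d <- stage1_delta(ma)
  expect_equal(d$delta, -0.4, tolerance = 1e-10)
  expect_equal(d$k_total, 3)
  expect_equal(d$k_nonenglish, 1)
  # flipping every effect flips the sign of dSMD
  ma2 <- make_ma("m1", "s1", "primary", c(0, 0, 0.4), rep(0.1, 3),
                 c(FALSE, FALSE, TRUE))
  expect_equal(stage1_delta(ma2)$delta, -d$delta, tolerance = 1e-10)
  # monolingual meta-analysis propagates the meta-regression error
  mono <- make_ma("m1", "s1", "primary", c(0, 0.1, 0.2), rep(0.1, 3),
                  rep(TRUE, 3))
  expect_error(stage1_delta(mono), "constant")
})

test_that("stage-1 estimates center on an injected bias", {
  set.seed(81)
  deltas <- replicate(60, {
    mas <- gen_metaepi(metaepi_config(K = 1, k_range = c(8, 12)))
    stage1_delta(mas[[1]])$delta
  })
  expect_lt(abs(mean(deltas) + 0.3), 3 * sd(deltas) / sqrt(60))
})

test_that("stage-2 pooling behaves under degenerate and heterogeneous inputs", {
  eq <- data.frame(ma_id = paste0("m", 1:3), sr_id = paste0("s", 1:3),
                   delta = rep(-0.25, 3), var_delta = rep(0.04, 3))
  r <- stage2_pool(eq, "random")
  f <- stage2_pool(eq, "fixed")
  expect_equal(r$pooled_delta, -0.25)
  expect_equal(f$pooled_delta, -0.25)
  expect_identical(f$kappa2, 0)
  expect_error(stage2_pool(eq[1, ], "random"), "at least 2")
  # strong between-MA spread: random CI strictly wider than fixed
  het <- data.frame(ma_id = paste0("m", 1:6), sr_id = paste0("s", 1:6),
                    delta = c(-1.2, -0.8, 0.1, 0.6, -0.3, 1.0),
                    var_delta = rep(0.02, 6))
  rh <- stage2_pool(het, "random")
  fh <- stage2_pool(het, "fixed")
  expect_gt(rh$kappa2, 0)
  expect_gt(rh$ci_high - rh$ci_low, fh$ci_high - fh$ci_low)
})

test_that("one meta-analysis per systematic review is enforced", {
  dup <- data.frame(ma_id = c("m1", "m2"), sr_id = c("s1", "s1"),
                    delta = c(-0.2, -0.3), var_delta = c(0.04, 0.05))
  expect_error(stage2_pool(dup, "random"), "same systematic review")
})

test_that("language-subset sensitivity contrasts all trials with English-only", {
  # homogeneous: dropping the non-English trial costs precision
  hom <- make_ma("m1", "s1", "primary", c(0.3, 0.31, 0.29, 0.3), rep(0.1, 4),
                 c(FALSE, FALSE, FALSE, TRUE))
  s <- language_subset_sensitivity(hom)
  expect_true(s$english_only_available)
  expect_gte(s$english_only$se, s$all$se)
  # outlying non-English trial inflates heterogeneity of the full set
  out <- make_ma("m2", "s2", "primary", c(0.3, 0.32, 0.28, 1.8), rep(0.08, 4),
                 c(FALSE, FALSE, FALSE, TRUE))
  s2 <- language_subset_sensitivity(out)
  expect_lt(s2$english_only$het$tau, s2$all$het$tau)
  # fewer than two English trials: subset flagged unavailable
  few <- make_ma("m3", "s3", "primary", c(0.1, 0.2, 0.3), rep(0.1, 3),
                 c(TRUE, TRUE, FALSE))
  s3 <- language_subset_sensitivity(few)
  expect_false(s3$english_only_available)
  expect_null(s3$english_only)
})

test_that("the langbias fit selects one meta-analysis per review and pools", {
  mas <- c(
    list(make_ma("m1a", "s1", "primary", c(0.1, 0.2), rep(0.1, 2),
                 c(FALSE, TRUE)),
         make_ma("m1b", "s1", "secondary", c(0.2, 0.1, -0.5), rep(0.1, 3),
                 c(FALSE, FALSE, TRUE))),
    gen_metaepi(metaepi_config(K = 6, seed = 82)))
  fit <- langbias(mas)
  expect_s3_class(fit, "langbias")
  expect_equal(fit$n_selected, 7)
  expect_true("m1b" %in% fit$stage1$ma_id)
  expect_false(anyDuplicated(fit$stage1$sr_id) > 0)
  expect_named(coef(fit), c("random", "fixed"))
  ci <- confint(fit)
  expect_true(ci["random", 1] <= coef(fit)[["random"]])
  expect_length(fit$sensitivity, 7)
  expect_output(print(fit), "pooled dSMD")
  expect_output(print(summary(fit)), "stage 1")
})
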