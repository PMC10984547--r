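test_that("trial generation is seed-deterministic and valid", {
  cfg <- metaepi_config(K = 6, seed = 101)
  a <- gen_metaepi(cfg)
  b <- gen_metaepi(cfg)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_trial_table(a, f1); write_trial_table(b, f2)
  expect_identical(readLines(f1), readLines(f2))
  # every generated table passes validation on re-read
  mas <- read_trial_table(f1)
  expect_length(mas, 6)
  for (ma in mas) {
    expect_gte(nrow(ma$trials), 3)
    expect_gte(sum(ma$trials$non_english), 1)
    expect_gte(sum(!ma$trials$non_english), 1)
  }
})

test_that("noise-free generation concentrates effects at the configured truth", {
  cfg <- metaepi_config(K = 30, sd_theta = 0, tau = 0, kappa = 0,
                        n_range = c(20000, 20000), seed = 102)
  mas <- gen_metaepi(cfg)
  tr <- do.call(rbind, lapply(mas, `[[`, "trials"))
  eff <- trial_effects(tr)
  en <- eff$y[!tr$non_english]
  ne <- eff$y[tr$non_english]
  expect_lt(sd(en), 0.02)
  expect_lt(sd(ne), 0.02)
  expect_equal(mean(en), 0.3, tolerance = 0.01)
  expect_equal(mean(ne), 0.0, tolerance = 0.01)   # 0.3 + delta
})

test_that("review-table generation follows its logistic model", {
  cfg <- sr_config(N = 2000, beta = c(intercept = qlogis(45 / 174)),
                   seed = 103)
  sr <- gen_sr_table(cfg)
  expect_lt(abs(mean(sr$non_english_included) - 45 / 174), 0.03)
  expect_true(all(!is.na(sr$n_retrieved)))
  expect_true(all(sr$n_retrieved >= sr$n_included))
})

test_that("forced separation breaks the MLE but not the Firth fit", {
  cfg <- sr_config(N = 300, force_separation = TRUE, seed = 104)
  sr <- gen_sr_table(cfg)
  expect_true(any(sr$excluded_nonenglish))
  expect_true(all(!sr$non_english_included[sr$excluded_nonenglish]))
  pc <- prepare_covariates(sr)
  d <- as.data.frame(pc$X[, -1])
  d$y <- pc$y
  mle <- suppressWarnings(glm(y ~ excluded_nonenglish, binomial, d))
  expect_gt(abs(coef(mle)[2]), 10)
  ff <- firth_logistic(y ~ excluded_nonenglish, d)
  expect_true(all(is.finite(coef(ff))))
  expect_true(ff$converged)
})

test_that("the packaged review fixture reproduces every published margin", {
  sr <- sr_fixture()
  expect_equal(nrow(sr), 174)
  expect_equal(sum(sr$non_english_included), 45)
  expect_equal(sum(sr$cochrane), 9)
  expect_equal(as.integer(table(sr$n_authors_band)), c(43, 111, 20))
  expect_equal(as.integer(table(sr$continent)), c(46, 51, 77))
  expect_equal(as.integer(table(sr$year)), c(28, 32, 29, 37, 48))
  expect_equal(sum(sr$prospero), 125)
  expect_equal(sum(sr$language_restriction, na.rm = TRUE), 33)
  expect_equal(sum(sr$language_restriction & sr$non_english_included,
                   na.rm = TRUE), 1)
  expect_equal(sum(is.na(sr$language_restriction)), 6)
  expect_equal(sum(sr$excluded_nonenglish), 4)
  expect_equal(sum(sr$librarian), 37)
  expect_equal(sum(sr$ma_performed), 97)
  expect_equal(as.integer(table(sr$sr_type)), c(9, 19, 146))
  expect_equal(as.integer(table(sr$study_type)), c(12, 159, 3))
  expect_equal(sum(sr$n_included), 2568)
  expect_equal(sum(sr$n_nonenglish_studies), 98)
  expect_equal(sum(is.na(sr$n_retrieved)), 1)
  expect_equal(sum(is.na(sr$n_nonenglish_langs[sr$non_english_included])), 1)
  # precision is exactly representable for every review that reports it
  p <- sr$n_included / sr$n_retrieved
  q <- quantile(p, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7, names = FALSE)
  expect_equal(q, c(0.01, 0.02, 0.04))
  expect_equal(range(p, na.rm = TRUE), c(0.001, 0.27))
  # fixture is deterministic
  expect_identical(sr, sr_fixture())
})

test_that("invalid generator configurations are rejected", {
  expect_error(metaepi_config(K = 5, k_range = c(2, 8)))
  expect_error(metaepi_config(K = 5, p_ne = 0))
  expect_error(sr_config(marginals = list(continent = c(a = 0.5, b = 0.2))),
               "sum to 1")
})
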