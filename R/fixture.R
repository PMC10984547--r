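# Synthetic deterministic fixtures reconstructing the published summary
# tables of the motivating survey of 174 orthodontic systematic reviews
# (2017-2021). Only the printed marginal counts and metric summaries are
# reproduced; the joint structure across fields is arbitrary but fixed and
# is NOT the survey's true row-level data (which was never deposited).

# per-group sorted numbers of included studies; totals 826 + 1742 = 2568
fixture_incl_yes <- c(4, 5, 6, 6, 7, 7, 8, 8, 9, 9, 9, 9, 10, 10, 11, 11,
                      12, 12, 12, 13, 13, 13, 13, 14, 14, 15, 15, 16, 17,
                      18, 19, 20, 21, 22, 22, 24, 26, 28, 30, 35, 40, 45,
                      50, 55, 63)

fixture_incl_no <- c(2, 3, 4, 4, 5, 5, 5, rep(6, 7), rep(7, 26), rep(8, 12),
                     rep(9, 8), rep(10, 10), rep(11, 8), rep(12, 6),
                     rep(13, 4), rep(14, 4), rep(15, 3), rep(16, 4),
                     rep(17, 4), 17:26, 27, 27, 28, 28, 29, 30, 30, 31, 31,
                     32, 33, 34, 35, 36, 37, 94)

# numbers of non-English studies in the 45 reviews that included any
# (sum 98); and of non-English languages (one not reported)
fixture_ne_studies <- c(rep(1, 23), rep(2, 10), rep(3, 9), 4, 5, 19)
fixture_ne_langs <- c(rep(1, 23), rep(2, 9), rep(3, 9), 4, 4, 19)

# precision value multisets per group; all exactly representable as
# n_included / n_retrieved for the paired review
fixture_prec_yes <- rep(c(0.001, 0.005, 0.01, 0.02, 0.04, 0.07, 0.1, 0.2,
                          0.26),
                        c(1, 9, 6, 12, 4, 4, 6, 1, 1))
fixture_prec_no <- rep(c(0.001, 0.005, 0.01, 0.02, 0.04, 0.05, 0.1, 0.2,
                         0.27),
                       c(2, 28, 25, 40, 20, 10, 2, 1, 1))

rep_levels <- function(levels, counts) rep(levels, counts)

# deterministic modular permutation (multiplier coprime with n); used to
# decorrelate the per-field assignments so the arbitrary joint layout does
# not create spurious exact collinearity between fields
mod_perm <- function(n, k) ((seq_len(n) - 1) * k) %% n + 1

scramble_fields <- function(df, fields, multipliers) {
  n <- nrow(df)
  for (i in seq_along(fields)) {
    df[[fields[i]]] <- df[[fields[i]]][mod_perm(n, multipliers[i])]
  }
  df
}

# assign precision values to reviews so that n_included / n_retrieved is
# exact: values needing a divisible n_included are placed first
assign_precision <- function(n_incl, prec_values, special, na_index = NULL) {
  n <- length(n_incl)
  prec <- rep(NA_real_, n)
  used <- logical(n)
  if (!is.null(na_index)) used[na_index] <- TRUE
  pool <- prec_values
  for (i in seq_len(nrow(special))) {
    idx <- which(!used & n_incl %% special$divisor[i] == 0)[1]
    prec[idx] <- special$p[i]
    used[idx] <- TRUE
    pool <- pool[-match(special$p[i], pool)]
  }
  prec[!used] <- pool
  prec
}

#' Deterministic review-characteristics fixture
#'
#' A fixed synthetic 174-row review table whose per-field marginal counts,
#' overall and split by inclusion of non-English studies, equal the
#' published summary table of the motivating survey, including the
#' footnoted missingness (search precision and number of non-English
#' languages not reported in one review; language-restriction status in
#' six). Metric fields reproduce the printed medians, quartiles (type 7)
#' and ranges, and total 2568 included studies of which 98 are non-English.
#' The joint distribution across fields is an arbitrary deterministic
#' layout, not the survey's true data.
#'
#' @return data frame of validated review records with the additional
#'   column `n_nonenglish_studies` (per-review count of non-English
#'   studies; 0 where none were included).
#' @examples
#' sr <- sr_fixture()
#' sum(sr$non_english_included)  # 45
#' @export
sr_fixture <- function() {
  yes <- data.frame(
    non_english_included = TRUE,
    n_authors_band = rep_levels(c("1-3", "4-6", "7-9"), c(13, 27, 5)),
    continent = rep_levels(c("America", "AsiaOther", "Europe"),
                           c(13, 11, 21)),
    cochrane = rep_levels(c(TRUE, FALSE), c(3, 42)),
    year = rep_levels(2017:2021, c(11, 6, 7, 12, 9)),
    prospero = rep_levels(c(FALSE, TRUE), c(7, 38)),
    n_included = fixture_incl_yes,
    language_restriction = rep_levels(c(FALSE, TRUE), c(44, 1)),
    excluded_nonenglish = FALSE,
    librarian = rep_levels(c(FALSE, TRUE), c(34, 11)),
    ma_performed = rep_levels(c(FALSE, TRUE), c(14, 31)),
    sr_type = rep_levels(c("diagnostic", "epidemiological", "interventional"),
                         c(1, 1, 43)),
    study_type = rep_levels(c("animal", "human", "invitro"), c(5, 40, 0)),
    stringsAsFactors = FALSE)
  # non-English study counts pair ascending with n_included so every count
  # fits inside its review
  yes$n_nonenglish_studies <- fixture_ne_studies
  # language counts: reviews with k non-English studies get at most k
  # languages; the review with missing language count also lacks precision
  lang <- integer(45)
  lang[1:23] <- 1L                     # one non-English study each
  lang[24:33] <- c(rep(2L, 9), NA)     # two studies; one review unreported
  lang[34:42] <- 3L                    # three studies
  lang[43] <- 4L                       # four studies
  lang[44] <- 4L                       # five studies
  lang[45] <- 19L                      # nineteen studies
  yes$n_nonenglish_langs <- lang
  na_idx <- which(is.na(lang))
  prec_yes <- assign_precision(
    yes$n_included, fixture_prec_yes,
    special = data.frame(p = c(0.07, 0.07, 0.07, 0.07, 0.26),
                         divisor = c(7, 7, 7, 7, 13)),
    na_index = na_idx)

  no <- data.frame(
    non_english_included = FALSE,
    n_authors_band = rep_levels(c("1-3", "4-6", "7-9"), c(30, 84, 15)),
    continent = rep_levels(c("America", "AsiaOther", "Europe"),
                           c(33, 40, 56)),
    cochrane = rep_levels(c(TRUE, FALSE), c(6, 123)),
    year = rep_levels(2017:2021, c(17, 26, 22, 25, 39)),
    prospero = rep_levels(c(FALSE, TRUE), c(42, 87)),
    n_included = fixture_incl_no,
    language_restriction = rep_levels(c(FALSE, TRUE, NA), c(91, 32, 6)),
    excluded_nonenglish = rep_levels(c(FALSE, TRUE), c(125, 4)),
    librarian = rep_levels(c(FALSE, TRUE), c(103, 26)),
    ma_performed = rep_levels(c(FALSE, TRUE), c(63, 66)),
    sr_type = rep_levels(c("diagnostic", "epidemiological", "interventional"),
                         c(8, 18, 103)),
    study_type = rep_levels(c("animal", "human", "invitro"), c(7, 119, 3)),
    stringsAsFactors = FALSE)
  no$n_nonenglish_studies <- 0L
  no$n_nonenglish_langs <- NA_integer_
  prec_no <- assign_precision(
    no$n_included, fixture_prec_no,
    special = data.frame(p = 0.27, divisor = 27))

  cat_fields <- c("n_authors_band", "continent", "cochrane", "year",
                  "prospero", "language_restriction", "excluded_nonenglish",
                  "librarian", "ma_performed", "sr_type", "study_type")
  # multipliers coprime with 45 and 129 respectively
  yes <- scramble_fields(yes, cat_fields,
                         c(7, 11, 13, 16, 17, 19, 22, 23, 26, 28, 29))
  no <- scramble_fields(no, cat_fields,
                        c(7, 11, 14, 16, 17, 19, 22, 23, 26, 28, 29))
  out <- rbind(yes, no)
  prec <- c(prec_yes, prec_no)
  out$n_retrieved <- ifelse(is.na(prec), NA_integer_,
                            as.integer(round(out$n_included / prec)))
  out$sr_id <- sprintf("sr%03d", seq_len(nrow(out)))
  out <- out[, c("sr_id", "n_authors_band", "continent", "cochrane", "year",
                 "prospero", "n_included", "n_retrieved",
                 "non_english_included", "n_nonenglish_studies",
                 "n_nonenglish_langs", "language_restriction",
                 "excluded_nonenglish", "librarian", "ma_performed",
                 "sr_type", "study_type")]
  rownames(out) <- NULL
  validate_sr(out)
}

#' Significance-by-language 2x2 counts
#'
#' The published cross-tabulation of statistical significance of the
#' summary estimate against inclusion of non-English studies, among the 29
#' reviews that performed a meta-analysis and reported study languages:
#' rows give reviews with/without non-English studies, columns significant
#' yes/no.
#'
#' @return 2x2 integer matrix with dimnames.
#' @export
significance_counts <- function() {
  matrix(c(16L, 4L, 5L, 4L), 2, 2, byrow = TRUE,
         dimnames = list(non_english = c("yes", "no"),
                         significant = c("yes", "no")))
}
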