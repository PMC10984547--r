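# Descriptive summaries of systematic-review characteristics and covariate
# preparation for the association model.

# categorical fields of the review table, with level order and the
# reference level used for dummy coding in the association model
sr_cat_fields <- list(
  n_authors_band = c("1-3", "4-6", "7-9"),
  continent = c("America", "AsiaOther", "Europe"),
  cochrane = c("yes", "no"),
  year = c("2017", "2018", "2019", "2020", "2021"),
  prospero = c("no", "yes"),
  language_restriction = c("no", "yes"),
  excluded_nonenglish = c("no", "yes"),
  librarian = c("no", "yes"),
  ma_performed = c("no", "yes"),
  sr_type = c("diagnostic", "epidemiological", "interventional"),
  study_type = c("animal", "human", "invitro"))

#' Search precision of a systematic review
#'
#' The number of included studies divided by the number of deduplicated
#' search records, a measure of search efficiency (e.g. 10 included out of
#' 1000 retrieved gives 0.01).
#'
#' @param n_included number of included studies (at least 1).
#' @param n_retrieved number of deduplicated search records (at least
#'   `n_included`).
#' @return precision in (0, 1\]; vectorized.
#' @export
search_precision <- function(n_included, n_retrieved) {
  if (any(n_included < 1, na.rm = TRUE)) {
    stop("n_included must be at least 1")
  }
  if (any(n_included > n_retrieved, na.rm = TRUE)) {
    stop("n_included cannot exceed n_retrieved")
  }
  n_included / n_retrieved
}

fmt_num <- function(x, digits = 2) formatC(x, format = "f", digits = digits)

metric_summary <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(list(median = NA, q1 = NA, q3 = NA,
                              min = NA, max = NA, n = 0L))
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3], min = min(x), max = max(x),
       n = length(x))
}

#' Summarize systematic-review characteristics
#'
#' Per categorical field: absolute and relative frequencies (percentages
#' rounded to integer), overall and split by inclusion of non-English
#' studies; per metric field: median (IQR) \[range\] with type-7 quartiles.
#' Percentages are computed over non-missing values in each column.
#'
#' @param records review-characteristics data frame (see
#'   [read_sr_table()]).
#' @return data frame (class `sr_summary`) with one row per level or metric,
#'   columns `field`, `level`, numeric counts/percentages per group and
#'   formatted display columns `overall`, `no`, `yes`.
#' @export
summarize_sr <- function(records) {
  stopifnot(nrow(records) >= 1)
  grp <- list(overall = rep(TRUE, nrow(records)),
              no = !records$non_english_included,
              yes = records$non_english_included)
  rows <- list()
  add_cat <- function(field, levels) {
    x <- records[[field]]
    x <- if (is.logical(x)) yn(x) else as.character(x)
    for (lv in levels) {
      r <- data.frame(field = field, level = lv, stringsAsFactors = FALSE)
      for (g in names(grp)) {
        xg <- x[grp[[g]]]
        n_nonmiss <- sum(!is.na(xg))
        n <- sum(xg == lv, na.rm = TRUE)
        pct <- if (n_nonmiss) round(100 * n / n_nonmiss) else NA
        r[[paste0("n_", g)]] <- n
        r[[paste0("pct_", g)]] <- pct
        r[[g]] <- sprintf("%d (%d%%)", n, pct)
      }
      rows[[length(rows) + 1L]] <<- r
    }
  }
  add_metric <- function(field, label, digits = 2) {
    x <- records[[field]]
    r <- data.frame(field = label, level = "median (IQR) [range]",
                    stringsAsFactors = FALSE)
    for (g in names(grp)) {
      s <- metric_summary(x[grp[[g]]])
      r[[paste0("n_", g)]] <- s$n
      r[[paste0("pct_", g)]] <- NA
      r[[g]] <- if (s$n) {
        sprintf("%s (%s, %s) [%s, %s]", fmt_num(s$median, digits),
                fmt_num(s$q1, digits), fmt_num(s$q3, digits),
                fmt_num(s$min, digits), fmt_num(s$max, digits))
      } else "NA"
    }
    rows[[length(rows) + 1L]] <<- r
  }
  add_cat("non_english_included", c("no", "yes"))
  for (f in names(sr_cat_fields)) {
    if (f %in% names(records)) add_cat(f, sr_cat_fields[[f]])
  }
  add_metric("n_included", "n_included")
  if (!is.null(records$n_retrieved)) {
    records$precision <- search_precision(records$n_included,
                                          records$n_retrieved)
    add_metric("precision", "precision", digits = 3)
  }
  if (!is.null(records$n_nonenglish_langs)) {
    add_metric("n_nonenglish_langs", "n_nonenglish_langs", digits = 0)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sr_summary", "data.frame")
  out
}

# boolean -> "yes"/"no" string used throughout the table layer
yn <- function(x) ifelse(is.na(x), NA_character_, ifelse(x, "yes", "no"))

#' Design matrix for the association model
#'
#' Builds the multivariable design associating review characteristics with
#' the inclusion of non-English studies: dummy columns against the reference
#' levels (first author band 1-3, continent America, Cochrane, no
#' registration, no restriction, no exclusion, no librarian, no
#' meta-analysis, diagnostic reviews, animal studies), number of included
#' studies as a metric column, search precision on the logit scale, and
#' publication year centred on its mean. Rows with a missing model covariate
#' are excluded (complete-case).
#'
#' @param records review-characteristics data frame.
#' @param clamp_eps precisions of exactly 1 are clamped to `1 - clamp_eps`
#'   before the logit (with a warning); values of exactly 0 cannot occur
#'   since at least one study is included.
#' @return list with `X` (design matrix including intercept), `y` (0/1
#'   response: non-English studies included), `n_dropped` and `rows`
#'   (indices of retained records).
#' @export
prepare_covariates <- function(records, clamp_eps = 1e-6) {
  prec <- search_precision(records$n_included, records$n_retrieved)
  if (any(prec >= 1, na.rm = TRUE)) {
    warning(sum(prec >= 1, na.rm = TRUE),
            " precision value(s) of 1 clamped before the logit transform")
    prec[!is.na(prec) & prec >= 1] <- 1 - clamp_eps
  }
  keep <- !is.na(prec) & !is.na(records$language_restriction)
  r <- records[keep, , drop = FALSE]
  prec <- prec[keep]
  X <- cbind(
    intercept = 1,
    authors4_6 = as.numeric(r$n_authors_band == "4-6"),
    authors7_9 = as.numeric(r$n_authors_band == "7-9"),
    continentAsiaOther = as.numeric(r$continent == "AsiaOther"),
    continentEurope = as.numeric(r$continent == "Europe"),
    noncochrane = as.numeric(!r$cochrane),
    year_centred = r$year - mean(r$year),
    prospero = as.numeric(r$prospero),
    n_included = r$n_included,
    logit_precision = stats::qlogis(prec),
    restriction = as.numeric(r$language_restriction),
    excluded_nonenglish = as.numeric(r$excluded_nonenglish),
    librarian = as.numeric(r$librarian),
    ma_performed = as.numeric(r$ma_performed),
    sr_epidemiological = as.numeric(r$sr_type == "epidemiological"),
    sr_interventional = as.numeric(r$sr_type == "interventional"),
    study_human = as.numeric(r$study_type == "human"),
    study_invitro = as.numeric(r$study_type == "invitro"))
  list(X = X, y = as.numeric(r$non_english_included),
       n_dropped = sum(!keep), rows = which(keep))
}

#' Share of non-English studies among all included studies
#'
#' @param records review-characteristics data frame with `n_included`.
#' @param per_sr_counts number of non-English studies per review, aligned
#'   with `records` rows.
#' @return percentage, \eqn{100 \sum \mathrm{nonEnglish} / \sum
#'   \mathrm{included}}.
#' @export
nonenglish_share <- function(records, per_sr_counts) {
  stopifnot(length(per_sr_counts) == nrow(records))
  denom <- sum(records$n_included)
  if (denom == 0) stop("zero total included studies")
  100 * sum(per_sr_counts) / denom
}
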