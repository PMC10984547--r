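# Reading, validation and writing of the two tabular inputs and the result
# tables. Conventions: comma-separated UTF-8 with a mandatory header,
# booleans written as yes/no, missing values as empty fields; row order is
# preserved throughout (forest plots keep the reported trial order).

parse_yn <- function(x, field, rows) {
  x <- trimws(as.character(x))
  out <- rep(NA, length(x))
  out[x %in% c("yes", "TRUE", "true")] <- TRUE
  out[x %in% c("no", "FALSE", "false")] <- FALSE
  bad <- !is.na(x) & x != "" & is.na(out)
  if (any(bad)) {
    stop("field '", field, "', row ", rows[which(bad)[1]],
         ": expected yes/no, got '", x[bad][1], "'")
  }
  out
}

check_level <- function(x, field, levels, rows) {
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad)) {
    stop("field '", field, "', row ", rows[which(bad)[1]],
         ": unknown level '", x[bad][1], "'; allowed: ",
         paste(levels, collapse = ", "))
  }
  x
}

#' Validate a trial-record table
#'
#' Enforces the trial-record invariants: every row is either arm-level
#' (both arms with mean, SD > 0, n >= 2) or contrast-level (`smd` with
#' `smd_se` > 0), never both; trial identifiers are unique within the
#' meta-analysis. Errors name the offending row and field.
#'
#' @param trials trial-record data frame.
#' @param ma_id meta-analysis label used in error messages; all rows must
#'   carry it.
#' @return the validated data frame, row order untouched.
#' @export
validate_trials <- function(trials, ma_id = trials$ma_id[1]) {
  req <- c("trial_id", "ma_id", "non_english", "data_level")
  miss <- setdiff(req, names(trials))
  if (length(miss)) stop("missing trial columns: ", paste(miss, collapse = ", "))
  if (!all(trials$ma_id == ma_id)) {
    stop("trials of meta-analysis ", ma_id, " carry mixed ma_id values")
  }
  if (anyDuplicated(trials$trial_id)) {
    stop("duplicated trial_id within meta-analysis ", ma_id, ": ",
         trials$trial_id[duplicated(trials$trial_id)][1])
  }
  check_level(trials$data_level, "data_level", c("arm", "contrast"),
              seq_len(nrow(trials)))
  if (any(is.na(trials$non_english))) {
    stop("meta-analysis ", ma_id, ": non_english flag missing in row ",
         which(is.na(trials$non_english))[1])
  }
  for (i in seq_len(nrow(trials))) {
    lab <- paste0("meta-analysis ", ma_id, ", row ", i,
                  " (trial ", trials$trial_id[i], ")")
    if (trials$data_level[i] == "arm") {
      arm <- unlist(trials[i, c("arm1_mean", "arm1_sd", "arm1_n",
                                "arm2_mean", "arm2_sd", "arm2_n")])
      if (any(is.na(arm))) stop(lab, ": incomplete arm block")
      if (!all(is.na(unlist(trials[i, c("smd", "smd_se")])))) {
        stop(lab, ": both arm and contrast blocks populated")
      }
      if (trials$arm1_sd[i] <= 0 || trials$arm2_sd[i] <= 0) {
        stop(lab, ": arm SD must be positive")
      }
      if (trials$arm1_n[i] < 2 || trials$arm2_n[i] < 2) {
        stop(lab, ": arm n must be at least 2")
      }
    } else {
      if (is.na(trials$smd[i]) || is.na(trials$smd_se[i])) {
        stop(lab, ": incomplete contrast block")
      }
      arm_cols <- c("arm1_mean", "arm1_sd", "arm1_n", "arm2_mean",
                    "arm2_sd", "arm2_n")
      present <- intersect(arm_cols, names(trials))
      if (length(present) && !all(is.na(unlist(trials[i, present])))) {
        stop(lab, ": both arm and contrast blocks populated")
      }
      if (trials$smd_se[i] <= 0) stop(lab, ": smd_se must be positive")
    }
  }
  trials
}

#' Read a meta-epidemiological trial table
#'
#' Expects a CSV with header columns `trial_id`, `ma_id`, `sr_id`,
#' `outcome_role`, `non_english` (yes/no), `data_level` (arm/contrast) and
#' either the arm block (`arm1_mean`, `arm1_sd`, `arm1_n`, `arm2_mean`,
#' `arm2_sd`, `arm2_n`) or the contrast block (`smd`, `smd_se`) per row.
#' Rows are grouped by `ma_id` (file order preserved) and validated.
#'
#' @param path CSV file path.
#' @return list of [ma_data()] objects.
#' @export
read_trial_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("trial_id", "ma_id", "sr_id", "outcome_role", "non_english",
           "data_level")
  miss <- setdiff(req, names(raw))
  if (length(miss)) stop("missing columns in ", path, ": ",
                         paste(miss, collapse = ", "))
  if (!nrow(raw)) {
    warning("empty trial table: ", path)
    return(list())
  }
  raw$non_english <- parse_yn(raw$non_english, "non_english", seq_len(nrow(raw)))
  check_level(raw$outcome_role, "outcome_role", c("primary", "secondary"),
              seq_len(nrow(raw)))
  for (col in c("arm1_mean", "arm1_sd", "arm1_n", "arm2_mean", "arm2_sd",
                "arm2_n", "smd", "smd_se")) {
    if (is.null(raw[[col]])) raw[[col]] <- NA_real_
    raw[[col]] <- as.numeric(raw[[col]])
  }
  lapply(split(raw, raw$ma_id)[unique(raw$ma_id)], function(tr) {
    if (length(unique(tr$sr_id)) != 1 || length(unique(tr$outcome_role)) != 1) {
      stop("meta-analysis ", tr$ma_id[1],
           ": inconsistent sr_id or outcome_role across rows")
    }
    ma_data(tr$ma_id[1], tr$sr_id[1], tr$outcome_role[1], tr)
  })
}

#' Write a meta-epidemiological trial table
#'
#' Inverse of [read_trial_table()]; round-trips to full precision.
#'
#' @param mas list of [ma_data()] objects.
#' @param path output CSV path.
#' @export
write_trial_table <- function(mas, path) {
  rows <- do.call(rbind, lapply(mas, function(ma) {
    tr <- ma$trials
    tr$sr_id <- ma$sr_id
    tr$outcome_role <- ma$outcome_role
    tr
  }))
  rows$non_english <- yn(rows$non_english)
  cols <- c("trial_id", "ma_id", "sr_id", "outcome_role", "non_english",
            "data_level", "arm1_mean", "arm1_sd", "arm1_n", "arm2_mean",
            "arm2_sd", "arm2_n", "smd", "smd_se")
  utils::write.csv(rows[, cols], path, row.names = FALSE, na = "",
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

validate_sr <- function(rec) {
  rows <- seq_len(nrow(rec))
  check_level(rec$n_authors_band, "n_authors_band",
              sr_cat_fields$n_authors_band, rows)
  check_level(rec$continent, "continent", sr_cat_fields$continent, rows)
  check_level(rec$sr_type, "sr_type", sr_cat_fields$sr_type, rows)
  check_level(rec$study_type, "study_type", sr_cat_fields$study_type, rows)
  bad_year <- !is.na(rec$year) & (rec$year < 2017 | rec$year > 2021)
  if (any(bad_year)) {
    stop("field 'year', row ", which(bad_year)[1], ": ",
         rec$year[bad_year][1], " outside the eligibility window 2017-2021")
  }
  if (any(is.na(rec$n_included)) || any(rec$n_included < 1)) {
    stop("n_included must be a positive integer for every review")
  }
  ok_ret <- is.na(rec$n_retrieved) | rec$n_retrieved >= rec$n_included
  if (!all(ok_ret)) {
    stop("field 'n_retrieved', row ", which(!ok_ret)[1],
         ": fewer retrieved than included records")
  }
  # missingness is allowed only where the source table footnotes it
  for (f in c("n_authors_band", "continent", "cochrane", "year", "prospero",
              "non_english_included", "excluded_nonenglish", "librarian",
              "ma_performed", "sr_type", "study_type")) {
    if (any(is.na(rec[[f]]))) {
      stop("field '", f, "', row ", which(is.na(rec[[f]]))[1],
           ": missing value not permitted")
    }
  }
  rec
}

#' Read a review-characteristics table
#'
#' CSV with header columns `sr_id`, `n_authors_band` (1-3/4-6/7-9),
#' `continent` (America/AsiaOther/Europe), `cochrane`, `year` (2017-2021),
#' `prospero`, `n_included`, `n_retrieved`, `non_english_included`,
#' `n_nonenglish_langs`, `language_restriction`, `excluded_nonenglish`,
#' `librarian`, `ma_performed`, `sr_type`
#' (diagnostic/epidemiological/interventional), `study_type`
#' (animal/human/invitro). Booleans are yes/no; missing values are empty
#' fields and are accepted only for `n_retrieved`, `n_nonenglish_langs` and
#' `language_restriction`.
#'
#' @param path CSV file path.
#' @return validated data frame, one row per review.
#' @export
read_sr_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!nrow(raw)) {
    warning("empty review table: ", path)
    return(raw)
  }
  raw[raw == ""] <- NA
  rows <- seq_len(nrow(raw))
  for (f in c("cochrane", "prospero", "non_english_included",
              "language_restriction", "excluded_nonenglish", "librarian",
              "ma_performed")) {
    raw[[f]] <- parse_yn(raw[[f]], f, rows)
  }
  for (f in c("year", "n_included", "n_retrieved", "n_nonenglish_langs",
              "n_nonenglish_studies")) {
    if (!is.null(raw[[f]])) {
      raw[[f]] <- suppressWarnings(as.integer(raw[[f]]))
    }
  }
  validate_sr(raw)
}

#' Write a review-characteristics table
#'
#' Inverse of [read_sr_table()].
#'
#' @param records review data frame.
#' @param path output CSV path.
#' @export
write_sr_table <- function(records, path) {
  out <- records
  for (f in c("cochrane", "prospero", "non_english_included",
              "language_restriction", "excluded_nonenglish", "librarian",
              "ma_performed")) {
    out[[f]] <- yn(out[[f]])
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write analysis result tables
#'
#' Writes each named element of `tables` under `out_dir`: data frames as
#' CSV; `bias_summary`, `pooled_estimate` and other list-like summaries as
#' both a one-row CSV and a machine-readable JSON. A stage-1 data frame
#' named `stage1` is additionally emitted as `forest.csv`
#' (ma_id, delta, ci_low, ci_high), ready for forest plotting.
#'
#' @param tables named list of result objects.
#' @param out_dir output directory, created if needed.
#' @return invisible character vector of the files written.
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(length(names(tables)) == length(tables))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  files <- character(0)
  for (nm in names(tables)) {
    x <- tables[[nm]]
    if (is.data.frame(x)) {
      if (!nrow(x)) stop("refusing to write empty table '", nm, "'")
      f <- file.path(out_dir, paste0(nm, ".csv"))
      utils::write.csv(x, f, row.names = FALSE, na = "")
      files <- c(files, f)
      if (nm == "stage1") {
        zq <- stats::qnorm(0.975)
        forest <- data.frame(ma_id = x$ma_id, delta = x$delta,
                             ci_low = x$delta - zq * sqrt(x$var_delta),
                             ci_high = x$delta + zq * sqrt(x$var_delta))
        ff <- file.path(out_dir, "forest.csv")
        utils::write.csv(forest, ff, row.names = FALSE)
        files <- c(files, ff)
      }
    } else {
      flat <- x[vapply(x, function(e) is.atomic(e) && length(e) == 1, TRUE)]
      f <- file.path(out_dir, paste0(nm, ".json"))
      jsonlite::write_json(flat, f, auto_unbox = TRUE, digits = NA)
      fc <- file.path(out_dir, paste0(nm, ".csv"))
      utils::write.csv(as.data.frame(flat), fc, row.names = FALSE)
      files <- c(files, f, fc)
    }
  }
  invisible(files)
}
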