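#' @title Cohort container
#' @description An `icu_cohort` bundles the per-patient basic profiles
#'   (sex, age, weight, height, BMI), the long-format monitored series
#'   (one row per patient x time, one column per monitored variable plus
#'   the labelling channels map / lactate / drug_present), and optional
#'   rule-based state labels. Every series patient_id must have a
#'   profile and vice versa.
#' @param profiles data frame with columns patient_id, sex, age, weight,
#'   height, bmi.
#' @param series data frame with columns patient_id, time, then one
#'   numeric column per monitored variable.
#' @param labels optional data frame patient_id, time, label.
#' @return an object of class `icu_cohort`.
#' @export
new_cohort <- function(profiles, series, labels = NULL) {
  obj <- structure(list(profiles = profiles, series = series,
                        labels = labels), class = "icu_cohort")
  validate_cohort(obj)
  obj
}

PROFILE_COLS <- c("patient_id", "sex", "age", "weight", "height", "bmi")

validate_cohort <- function(cohort) {
  p <- cohort$profiles; s <- cohort$series
  miss <- setdiff(PROFILE_COLS, names(p))
  if (length(miss))
    icp_stop(paste("profiles missing columns:", paste(miss, collapse = ", ")),
             "schema_error")
  if (!all(c("patient_id", "time") %in% names(s)))
    icp_stop("series missing patient_id/time columns", "schema_error")
  if (nrow(p) && any(!(c(p$age, p$weight, p$height, p$bmi) > 0), na.rm = TRUE))
    icp_stop("profiles contain non-positive age/weight/height/bmi",
             "schema_error")
  only_s <- setdiff(unique(s$patient_id), p$patient_id)
  only_p <- setdiff(p$patient_id, unique(s$patient_id))
  if (length(only_s) || length(only_p))
    icp_stop(sprintf(
      "referential integrity violated: %d series ids without profile, %d profiles without series",
      length(only_s), length(only_p)), "integrity_error")
  # time indices must start at 1, be consecutive and unique per patient
  if (nrow(s)) {
    bad <- vapply(split(s$time, s$patient_id), function(tt) {
      !identical(as.integer(sort(tt)), seq_along(tt)) || length(tt) < 2L
    }, logical(1))
    if (any(bad))
      icp_stop(paste("non-consecutive, duplicated, or too-short (< 2) time",
                     "index for patients:",
                     paste(head(names(bad)[bad], 5), collapse = ", ")),
               "schema_error")
  }
  invisible(cohort)
}

#' @export
print.icu_cohort <- function(x, ...) {
  cat(sprintf("<icu_cohort> %d patients, %d series rows, %d variables%s\n",
              nrow(x$profiles), nrow(x$series),
              length(monitored_var_names(x$series)),
              if (is.null(x$labels)) "" else ", labelled"))
  invisible(x)
}

monitored_var_names <- function(series) {
  setdiff(names(series), c("patient_id", "time", "lactate", "drug_present"))
}

#' Read a cohort from CSV files
#'
#' Reads the profiles and series tables, drops any patient with a missing
#' value in a required field (reporting the count), and checks referential
#' integrity between the two tables.
#'
#' @param profiles_path CSV with columns patient_id,sex,age,weight,height,bmi.
#' @param series_path CSV with columns patient_id,time,<variables...>;
#'   labelling channels map, lactate, drug_present are recognised when
#'   present (drug_present coded 0/1).
#' @param quiet suppress the dropped-row report.
#' @return an `icu_cohort`.
#' @export
read_cohort <- function(profiles_path, series_path, quiet = FALSE) {
  profiles <- read_checked_csv(profiles_path, PROFILE_COLS,
                               numeric_cols = setdiff(PROFILE_COLS, "patient_id"))
  series <- read_checked_csv(series_path, c("patient_id", "time"),
                             numeric_cols = NULL)
  for (cn in setdiff(names(series), "patient_id")) {
    series[[cn]] <- check_numeric_column(series[[cn]], cn, series_path)
  }
  # missing-value policy: drop the whole patient (not the row)
  bad_profile <- profiles$patient_id[!complete.cases(profiles)]
  bad_series <- unique(series$patient_id[!complete.cases(series)])
  drop_ids <- union(bad_profile, bad_series)
  if (length(drop_ids) && !quiet)
    message(sprintf("read_cohort: dropped %d patient(s) with missing values",
                    length(drop_ids)))
  profiles <- profiles[!(profiles$patient_id %in% drop_ids), , drop = FALSE]
  series <- series[!(series$patient_id %in% drop_ids), , drop = FALSE]
  new_cohort(profiles, series)
}

read_checked_csv <- function(path, required, numeric_cols) {
  if (!file.exists(path))
    icp_stop(paste("file not found:", path), "io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    icp_stop(sprintf("%s missing required columns: %s", path,
                     paste(miss, collapse = ", ")), "schema_error")
  for (cn in intersect(numeric_cols, names(df))) {
    df[[cn]] <- check_numeric_column(df[[cn]], cn, path)
  }
  df
}

check_numeric_column <- function(x, name, path) {
  if (is.numeric(x)) return(x)
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "" & is.na(out))
  if (length(bad))
    icp_stop(sprintf("%s: non-numeric value in column '%s' at data row %d",
                     path, name, bad[1]), "parse_error")
  out
}

#' Write a cohort (and optionally ground truth) to CSV files
#'
#' Writes `profiles.csv` and `series.csv` (plus `labels.csv` if labels are
#' present) under `dir`; write then [read_cohort()] round-trips up to
#' float text precision.
#'
#' @param cohort an `icu_cohort`.
#' @param dir output directory (created if needed).
#' @param truth optional `icu_truth`; written as `ground_truth.csv`.
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(profiles = file.path(dir, "profiles.csv"),
             series = file.path(dir, "series.csv"))
  utils::write.csv(cohort$profiles, paths["profiles"], row.names = FALSE)
  utils::write.csv(cohort$series, paths["series"], row.names = FALSE)
  if (!is.null(cohort$labels)) {
    paths["labels"] <- file.path(dir, "labels.csv")
    utils::write.csv(cohort$labels, paths["labels"], row.names = FALSE)
  }
  if (!is.null(truth)) {
    paths["ground_truth"] <- file.path(dir, "ground_truth.csv")
    utils::write.csv(truth$params, paths["ground_truth"], row.names = FALSE)
  }
  invisible(paths)
}

#' Rule-based circulatory-failure labels
#'
#' Labels each time point `failure` iff MAP <= `map_threshold` (inclusive)
#' OR (non-exclusively) vasoactive/inotropic drugs are present AND lactate
#' is strictly greater than `lactate_threshold`; otherwise `safe`.
#'
#' @param series a series data frame with numeric `map`, `lactate` and
#'   0/1 `drug_present` columns.
#' @param map_threshold mmHg; default 65.
#' @param lactate_threshold mmol/l; default 2.
#' @return data frame patient_id, time, label ("safe"/"failure").
#' @export
#' @examples
#' s <- data.frame(patient_id = "a", time = 1:3,
#'                 map = c(60, 80, 80), lactate = c(1, 2.5, 2),
#'                 drug_present = c(0, 1, 1))
#' label_states(s)$label  # failure, failure, safe
label_states <- function(series, map_threshold = 65, lactate_threshold = 2) {
  need <- c("map", "lactate", "drug_present")
  miss <- setdiff(need, names(series))
  if (length(miss))
    icp_stop(paste("series missing labelling channels:",
                   paste(miss, collapse = ", ")), "schema_error")
  for (cn in need) {
    if (!is.numeric(series[[cn]]) && !is.logical(series[[cn]]))
      icp_stop(paste("labelling channel not numeric:", cn), "schema_error")
  }
  failure <- series$map <= map_threshold |
    (as.logical(series$drug_present) & series$lactate > lactate_threshold)
  data.frame(patient_id = series$patient_id, time = series$time,
             label = ifelse(failure, "failure", "safe"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Keep only patients whose labels contain both classes
#'
#' Patients whose label series is all-safe or all-failure carry no ranking
#' information and are excluded from AUC measurement; this returns the
#' sub-cohort of patients with both classes present.
#'
#' @param cohort an `icu_cohort` with `labels` set.
#' @param quiet suppress the kept/dropped report.
#' @return the filtered `icu_cohort`.
#' @export
filter_multistate_patients <- function(cohort, quiet = FALSE) {
  if (is.null(cohort$labels))
    icp_stop("cohort has no labels; call label_states() first", "state_error")
  nclass <- vapply(split(cohort$labels$label, cohort$labels$patient_id),
                   function(l) length(unique(l)), integer(1))
  keep <- names(nclass)[nclass == 2L]
  if (!quiet)
    message(sprintf("filter_multistate_patients: kept %d of %d patients",
                    length(keep), length(nclass)))
  new_cohort(
    profiles = cohort$profiles[cohort$profiles$patient_id %in% keep, ,
                               drop = FALSE],
    series = cohort$series[cohort$series$patient_id %in% keep, ,
                           drop = FALSE],
    labels = cohort$labels[cohort$labels$patient_id %in% keep, ,
                           drop = FALSE])
}
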