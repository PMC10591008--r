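# Plain-text persistence for longitudinal datasets.
#
# A dataset is written as up to four CSVs in one directory:
#   records.csv     participant_id, session_index, acquisition_week,
#                   bundle, measure, value
#   covariates.csv  participant_id, age, sex, disease_duration
#   clinical.csv    participant_id, score_name, baseline_value,
#                   followup_value
#   truth.csv       participant_id, bundle, measure, true_slope
#                   (simulator ground truth; absent for real data)

RECORD_COLS <- c("participant_id", "session_index", "acquisition_week",
                 "bundle", "measure", "value")

#' Write a longitudinal dataset to a directory of CSV files
#'
#' @param dataset a `longitudinal_dataset`.
#' @param path directory to create/fill.
#' @return `path`, invisibly.
#' @seealso [read_dataset()]
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "longitudinal_dataset"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write.csv(dataset$records, file.path(path, "records.csv"),
            row.names = FALSE)
  if (!is.null(dataset$covariates)) {
    write.csv(dataset$covariates, file.path(path, "covariates.csv"),
              row.names = FALSE)
  }
  if (!is.null(dataset$clinical)) {
    write.csv(dataset$clinical, file.path(path, "clinical.csv"),
              row.names = FALSE)
  }
  if (!is.null(dataset$truth)) {
    write.csv(dataset$truth, file.path(path, "truth.csv"), row.names = FALSE)
  }
  jsonlite::write_json(list(session_weeks = dataset$session_weeks),
                       file.path(path, "meta.json"), digits = NA)
  invisible(path)
}

#' Read a longitudinal dataset written by [write_dataset()]
#'
#' Validates the schema on the way in: the records table must contain the
#' documented columns, baseline sessions must sit at week 0, and acquisition
#' weeks must increase within participant.
#'
#' @param path directory produced by [write_dataset()].
#' @return a `longitudinal_dataset`.
#' @export
read_dataset <- function(path) {
  rec_file <- file.path(path, "records.csv")
  if (!file.exists(rec_file)) {
    stop_config("no records.csv under '%s'", path)
  }
  records <- read.csv(rec_file, stringsAsFactors = FALSE)
  missing_cols <- setdiff(RECORD_COLS, names(records))
  if (length(missing_cols) > 0) {
    stop_config("records.csv is missing required column(s): %s",
                paste(missing_cols, collapse = ", "))
  }
  if (nrow(records) == 0) {
    warning("records table is empty", call. = FALSE)
  }
  validate_records(records)

  read_opt <- function(f) {
    fp <- file.path(path, f)
    if (file.exists(fp)) read.csv(fp, stringsAsFactors = FALSE) else NULL
  }
  meta <- file.path(path, "meta.json")
  session_weeks <- if (file.exists(meta)) {
    as.numeric(jsonlite::read_json(meta, simplifyVector = TRUE)$session_weeks)
  } else if (nrow(records) == 0) {
    numeric(0)
  } else {
    sw <- aggregate(acquisition_week ~ session_index, records, stats::median)
    sw$acquisition_week[order(sw$session_index)]
  }
  structure(
    list(records = records, covariates = read_opt("covariates.csv"),
         clinical = read_opt("clinical.csv"), truth = read_opt("truth.csv"),
         session_weeks = session_weeks),
    class = "longitudinal_dataset"
  )
}

validate_records <- function(records) {
  if (nrow(records) == 0) return(invisible(records))
  if (!is.numeric(records$value)) {
    stop_config("column 'value' must be numeric")
  }
  base <- records[records$session_index == 0, ]
  if (any(abs(base$acquisition_week) > 1e-9)) {
    bad <- base$participant_id[abs(base$acquisition_week) > 1e-9][1]
    stop_config("baseline acquisition_week must be 0 (participant %s)", bad)
  }
  # One value per (participant, session, bundle, measure).
  key <- paste(records$participant_id, records$session_index,
               records$bundle, records$measure, sep = "\r")
  if (anyDuplicated(key)) {
    stop_config("duplicate (participant, session, bundle, measure) rows")
  }
  # Acquisition weeks strictly increasing along sessions within participant.
  one <- records[records$bundle == records$bundle[1] &
                   records$measure == records$measure[1], ]
  one <- one[order(one$participant_id, one$session_index), ]
  dec <- stats::ave(one$acquisition_week, one$participant_id,
                    FUN = function(w) c(1, diff(w)))
  if (any(dec <= 0)) {
    stop_config("acquisition_week must be strictly increasing within participant")
  }
  invisible(records)
}
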