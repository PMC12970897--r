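#' Construct an SRS dataset
#'
#' The canonical in-memory representation of a spontaneous reporting
#' system extract: one case (demographic) table, one drug table and one
#' event table, linked by `report_id`, plus the source dialect.
#'
#' @param cases tibble with columns `report_id`, `case_id`, `version_key`,
#'   `age` (years), `sex` (`"female"|"male"|"unknown"`), `weight` (kg),
#'   `event_year`, `country`, `reporter`, `outcomes` (`";"`-joined set).
#' @param drugs tibble with columns `report_id`, `verbatim_name`,
#'   `ingredient` (NA until normalized), `role` (one of
#'   `"PS","SS","concomitant","interacting","suspect"`), `start_date`
#'   (`Date`), `start_imputed` (logical), `indication_pt`.
#' @param events tibble with columns `report_id`, `pt`, `onset_date`
#'   (`Date`), `onset_imputed` (logical).
#' @param dialect one of `"faers"`, `"jader"`, `"cvar"`, `"synthetic"`.
#' @param check validate invariants (default `TRUE`).
#' @return an object of class `srs_dataset`.
#' @export
srs_dataset <- function(cases, drugs, events,
                        dialect = c("faers", "jader", "cvar", "synthetic"),
                        check = TRUE) {
  dialect <- match.arg(dialect)
  cases <- fill_case_cols(tibble::as_tibble(cases))
  drugs <- fill_drug_cols(tibble::as_tibble(drugs))
  events <- fill_event_cols(tibble::as_tibble(events))
  ds <- structure(
    list(dialect = dialect, cases = cases, drugs = drugs, events = events),
    class = "srs_dataset"
  )
  if (check) validate_srs_dataset(ds)
  ds
}

case_cols <- c(report_id = "character", case_id = "character",
               version_key = "character", age = "numeric", sex = "character",
               weight = "numeric", event_year = "integer",
               country = "character", reporter = "character",
               outcomes = "character")
drug_cols <- c(report_id = "character", verbatim_name = "character",
               ingredient = "character", role = "character",
               start_date = "Date", start_imputed = "logical",
               indication_pt = "character")
event_cols <- c(report_id = "character", pt = "character",
                onset_date = "Date", onset_imputed = "logical")

fill_cols <- function(df, spec) {
  for (nm in names(spec)) {
    if (!nm %in% names(df)) {
      df[[nm]] <- switch(spec[[nm]],
        character = NA_character_, numeric = NA_real_, integer = NA_integer_,
        logical = NA, Date = as.Date(NA))
    }
  }
  df[names(spec)]
}
fill_case_cols <- function(df) {
  df <- fill_cols(df, case_cols)
  df$report_id <- as.character(df$report_id)
  df$case_id <- as.character(df$case_id)
  df$version_key <- as.character(df$version_key)
  df$age <- as.numeric(df$age)
  df$weight <- as.numeric(df$weight)
  df$event_year <- as.integer(df$event_year)
  df
}
fill_drug_cols <- function(df) {
  df <- fill_cols(df, drug_cols)
  df$report_id <- as.character(df$report_id)
  df$start_date <- as.Date(df$start_date)
  df
}
fill_event_cols <- function(df) {
  df <- fill_cols(df, event_cols)
  df$report_id <- as.character(df$report_id)
  df$onset_date <- as.Date(df$onset_date)
  df
}

srs_roles <- c("PS", "SS", "concomitant", "interacting", "suspect")

validate_srs_dataset <- function(ds) {
  cases <- ds$cases; drugs <- ds$drugs; events <- ds$events
  if (any(is.na(cases$report_id) | cases$report_id == "")) {
    abort("every case needs a non-empty report_id")
  }
  if (anyDuplicated(cases$report_id)) {
    abort("cases must hold exactly one record per report_id")
  }
  bad_age <- !is.na(cases$age) & cases$age < 0
  if (any(bad_age)) abort("age must be >= 0 when present")
  bad_wt <- !is.na(cases$weight) & cases$weight <= 0
  if (any(bad_wt)) abort("weight must be > 0 when present")
  bad_role <- !is.na(drugs$role) & !drugs$role %in% srs_roles
  if (any(bad_role)) {
    abort(paste0("unknown drug role(s): ",
                 paste(unique(drugs$role[bad_role]), collapse = ", ")))
  }
  orphan_d <- setdiff(drugs$report_id, cases$report_id)
  orphan_e <- setdiff(events$report_id, cases$report_id)
  if (length(orphan_d) || length(orphan_e)) {
    abort(paste0(
      "drug/event rows reference report ids absent from the case table: ",
      paste(utils::head(unique(c(orphan_d, orphan_e)), 20), collapse = ", ")
    ))
  }
  invisible(ds)
}

#' @export
print.srs_dataset <- function(x, ...) {
  cat(sprintf("<srs_dataset: %s> %d reports, %d drug rows, %d event rows\n",
              x$dialect, nrow(x$cases), nrow(x$drugs), nrow(x$events)))
  dd <- attr(x, "dedup")
  if (!is.null(dd)) {
    cat(sprintf("  deduplicated: %d removed (%d case versions, %d drug rows, %d event rows)\n",
                dd$n_removed, dd$n_case_versions, dd$n_drug_rows, dd$n_event_rows))
  }
  invisible(x)
}

#' Number of reports in a dataset
#' @param ds an `srs_dataset`.
#' @return integer count of case records.
#' @export
n_reports <- function(ds) nrow(ds$cases)

#' Write / read the canonical columnar format
#'
#' Persists an `srs_dataset` as three CSV files plus a small JSON header
#' recording the dialect; `read_srs(dir, dialect = "synthetic")` reads the
#' same layout back and round-trips all fields.
#'
#' @param ds an `srs_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_srs <- function(ds, dir) {
  stopifnot(inherits(ds, "srs_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(ds$cases, file.path(dir, "cases.csv"), na = "")
  readr::write_csv(ds$drugs, file.path(dir, "drugs.csv"), na = "")
  readr::write_csv(ds$events, file.path(dir, "events.csv"), na = "")
  jsonlite::write_json(list(dialect = ds$dialect), file.path(dir, "meta.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

read_srs_canonical <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  spec_of <- function(types) {
    do.call(readr::cols, lapply(types, function(t) switch(t,
      character = readr::col_character(), numeric = readr::col_double(),
      integer = readr::col_integer(), logical = readr::col_logical(),
      Date = readr::col_date())))
  }
  rd <- function(f, types) readr::read_csv(
    file.path(dir, f), col_types = spec_of(as.list(types)), na = "",
    progress = FALSE)
  srs_dataset(
    cases = rd("cases.csv", case_cols),
    drugs = rd("drugs.csv", drug_cols),
    events = rd("events.csv", event_cols),
    dialect = meta$dialect
  )
}
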