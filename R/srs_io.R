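#' Read a spontaneous reporting system extract
#'
#' Parses one of three SRS table dialects into the canonical
#' [srs_dataset()] form:
#'
#' * `"faers"` — FAERS quarterly ASCII: `$`-delimited files `DEMO*`,
#'   `DRUG*`, `REAC*` (required) and `THER*`, `INDI*`, `OUTC*` (optional)
#'   in `path`, with the standard column names (`primaryid`, `caseid`,
#'   `fda_dt`, `role_cod`, `drugname`, `pt`, ...).
#' * `"jader"` — CSV files `demo.csv`, `drug.csv`, `reac.csv` (and
#'   optionally `hist.csv`) linked by `caseid`, with romanized column
#'   names (`caseid`, `sex`, `age`, `weight`, `reporter`; `drugname`,
#'   `role`, `start_date`, `indication`; `pt`, `onset_date`).
#' * `"cvar"` — CSV files `reports.csv`, `report_drug.csv`,
#'   `reactions.csv` linked by `report_id` (the `Report_ID` spelling is
#'   accepted).
#' * `"synthetic"` — the canonical columnar layout written by
#'   [write_srs()].
#'
#' Unknown columns are tolerated; missing mandatory columns raise an
#' error naming the file and column. Dates are normalized to ISO, with
#' partial dates imputed to the 1st (flagged via `*_imputed`) and
#' unparseable dates set to `NA` and counted in the `n_date_failures`
#' attribute of the result.
#'
#' @param path directory containing the dialect's files.
#' @param dialect one of `"faers"`, `"jader"`, `"cvar"`, `"synthetic"`.
#' @return an [srs_dataset()].
#' @export
read_srs <- function(path, dialect = c("faers", "jader", "cvar", "synthetic")) {
  dialect <- match.arg(dialect)
  switch(dialect,
    faers = read_srs_faers(path),
    jader = read_srs_jader(path),
    cvar = read_srs_cvar(path),
    synthetic = read_srs_canonical(path)
  )
}

find_table <- function(dir, prefix, required = TRUE) {
  files <- list.files(dir, full.names = TRUE)
  hit <- files[grepl(paste0("^", prefix), basename(files), ignore.case = TRUE)]
  if (!length(hit)) {
    if (required) abort(sprintf("no %s* table found in %s", prefix, dir))
    return(NULL)
  }
  hit[[1]]
}

read_delim_table <- function(file, delim) {
  df <- readr::read_delim(file, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), na = c("", "NA"), progress = FALSE,
    trim_ws = TRUE)
  names(df) <- tolower(names(df))
  df
}

need_cols <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("file %s is missing mandatory column(s): %s",
                  basename(file), paste(missing, collapse = ", ")))
  }
  df
}

col_or_na <- function(df, col) {
  if (col %in% names(df)) df[[col]] else rep(NA_character_, nrow(df))
}

# -- FAERS ------------------------------------------------------------------

faers_age_years <- function(age, cod) {
  a <- suppressWarnings(as.numeric(age))
  cod <- toupper(ifelse(is.na(cod), "YR", cod))
  mult <- dplyr::case_when(
    cod %in% c("YR", "YEAR") ~ 1,
    cod == "DEC" ~ 10,
    cod %in% c("MON", "MO") ~ 1 / 12,
    cod == "WK" ~ 1 / 52.18,
    cod == "DY" ~ 1 / 365.25,
    cod == "HR" ~ 1 / 8766,
    TRUE ~ 1
  )
  a * mult
}

faers_outcome_map <- c(DE = "death", LT = "life-threatening",
                       HO = "hospitalization", DS = "disability",
                       CA = "other", RI = "other", OT = "other")

read_srs_faers <- function(dir) {
  demo_f <- find_table(dir, "DEMO")
  drug_f <- find_table(dir, "DRUG")
  reac_f <- find_table(dir, "REAC")
  ther_f <- find_table(dir, "THER", required = FALSE)
  indi_f <- find_table(dir, "INDI", required = FALSE)
  outc_f <- find_table(dir, "OUTC", required = FALSE)

  demo <- dplyr::distinct(need_cols(read_delim_table(demo_f, "$"),
                    c("primaryid", "caseid", "fda_dt"), demo_f))
  drug <- need_cols(read_delim_table(drug_f, "$"),
                    c("primaryid", "drugname", "role_cod"), drug_f)
  reac <- need_cols(read_delim_table(reac_f, "$"), c("primaryid", "pt"), reac_f)

  n_fail <- 0L
  fda_dt <- parse_srs_date(demo$fda_dt)
  event_dt <- parse_srs_date(col_or_na(demo, "event_dt"))
  n_fail <- n_fail + attr(fda_dt, "n_failed") + attr(event_dt, "n_failed")

  outcomes <- rep(NA_character_, nrow(demo))
  if (!is.null(outc_f)) {
    outc <- need_cols(read_delim_table(outc_f, "$"),
                      c("primaryid", "outc_cod"), outc_f)
    oc <- outc |>
      dplyr::mutate(outcome = unname(faers_outcome_map[toupper(.data$outc_cod)])) |>
      dplyr::filter(!is.na(.data$outcome)) |>
      dplyr::distinct(.data$primaryid, .data$outcome) |>
      dplyr::group_by(.data$primaryid) |>
      dplyr::summarise(outcomes = paste(sort(.data$outcome), collapse = ";"))
    outcomes <- oc$outcomes[match(demo$primaryid, oc$primaryid)]
  }

  sex <- dplyr::case_when(
    toupper(col_or_na(demo, "sex")) == "F" ~ "female",
    toupper(col_or_na(demo, "sex")) == "M" ~ "male",
    TRUE ~ "unknown"
  )
  reporter <- dplyr::case_when(
    toupper(col_or_na(demo, "occp_cod")) == "MD" ~ "physician",
    toupper(col_or_na(demo, "occp_cod")) == "PH" ~ "pharmacist",
    toupper(col_or_na(demo, "occp_cod")) == "HP" ~ "other health professional",
    toupper(col_or_na(demo, "occp_cod")) == "OT" ~ "other health professional",
    toupper(col_or_na(demo, "occp_cod")) %in% c("CN", "LW") ~ "non-health professional",
    TRUE ~ "unknown"
  )
  fda_digits <- format(as.Date(fda_dt), "%Y%m%d")
  fda_digits[is.na(fda_digits)] <- "00000000"
  cases <- tibble::tibble(
    report_id = demo$primaryid,
    case_id = demo$caseid,
    version_key = paste0(fda_digits, "#", pad_key(demo$primaryid)),
    age = faers_age_years(col_or_na(demo, "age"), col_or_na(demo, "age_cod")),
    sex = sex,
    weight = suppressWarnings(as.numeric(col_or_na(demo, "wt"))),
    event_year = as.integer(format(
      dplyr::coalesce(as.Date(event_dt), as.Date(fda_dt)), "%Y")),
    country = col_or_na(demo, "occr_country"),
    reporter = reporter,
    outcomes = outcomes
  )

  role <- dplyr::case_when(
    toupper(drug$role_cod) == "PS" ~ "PS",
    toupper(drug$role_cod) == "SS" ~ "SS",
    toupper(drug$role_cod) == "C" ~ "concomitant",
    toupper(drug$role_cod) == "I" ~ "interacting",
    TRUE ~ NA_character_
  )
  drug_seq <- col_or_na(drug, "drug_seq")

  start_date <- rep(as.Date(NA), nrow(drug))
  start_imputed <- rep(NA, nrow(drug))
  if (!is.null(ther_f)) {
    ther <- need_cols(read_delim_table(ther_f, "$"),
                      c("primaryid", "start_dt"), ther_f)
    sd <- parse_srs_date(ther$start_dt)
    n_fail <- n_fail + attr(sd, "n_failed")
    ther_tab <- tibble::tibble(
      primaryid = ther$primaryid,
      seq = col_or_na(ther, "dsg_drug_seq"),
      start_date = as.Date(sd),
      start_imputed = attr(sd, "imputed")
    )
    if (!all(is.na(ther_tab$seq)) && !all(is.na(drug_seq))) {
      key <- paste(drug$primaryid, drug_seq, sep = "\r")
      tt <- ther_tab |>
        dplyr::filter(!is.na(.data$start_date)) |>
        dplyr::arrange(.data$start_date) |>
        dplyr::distinct(key = paste(.data$primaryid, .data$seq, sep = "\r"),
                        .keep_all = TRUE)
      idx <- match(key, tt$key)
    } else {
      tt <- ther_tab |>
        dplyr::filter(!is.na(.data$start_date)) |>
        dplyr::arrange(.data$start_date) |>
        dplyr::distinct(.data$primaryid, .keep_all = TRUE)
      idx <- match(drug$primaryid, tt$primaryid)
    }
    start_date <- tt$start_date[idx]
    start_imputed <- tt$start_imputed[idx]
  }

  indication <- rep(NA_character_, nrow(drug))
  if (!is.null(indi_f)) {
    indi <- need_cols(read_delim_table(indi_f, "$"),
                      c("primaryid", "indi_pt"), indi_f)
    iseq <- col_or_na(indi, "indi_drug_seq")
    if (!all(is.na(iseq)) && !all(is.na(drug_seq))) {
      key <- paste(drug$primaryid, drug_seq, sep = "\r")
      it <- dplyr::distinct(tibble::tibble(
        key = paste(indi$primaryid, iseq, sep = "\r"), pt = indi$indi_pt), .data$key,
        .keep_all = TRUE)
      indication <- it$pt[match(key, it$key)]
    } else {
      it <- dplyr::distinct(tibble::tibble(primaryid = indi$primaryid,
                                           pt = indi$indi_pt),
                            .data$primaryid, .keep_all = TRUE)
      indication <- it$pt[match(drug$primaryid, it$primaryid)]
    }
  }

  drugs <- tibble::tibble(
    report_id = drug$primaryid,
    verbatim_name = drug$drugname,
    ingredient = NA_character_,
    role = role,
    start_date = start_date,
    start_imputed = start_imputed,
    indication_pt = indication
  )
  onset <- as.Date(event_dt)[match(reac$primaryid, demo$primaryid)]
  onset_imp <- attr(event_dt, "imputed")[match(reac$primaryid, demo$primaryid)]
  events <- tibble::tibble(
    report_id = reac$primaryid,
    pt = reac$pt,
    onset_date = onset,
    onset_imputed = onset_imp
  )
  ds <- srs_dataset(cases, drugs, events, dialect = "faers")
  attr(ds, "n_date_failures") <- n_fail
  if (n_fail > 0) warn(sprintf("%d date field(s) could not be parsed and were set to NA", n_fail))
  ds
}

# -- JADER ------------------------------------------------------------------

jader_role <- function(x) {
  xl <- norm_label(x)
  dplyr::case_when(
    grepl("suspect|被疑", xl) ~ "suspect",
    grepl("interact|相互", xl) ~ "interacting",
    grepl("concomitant|併用", xl) ~ "concomitant",
    TRUE ~ NA_character_
  )
}

read_srs_jader <- function(dir) {
  demo_f <- find_table(dir, "demo")
  drug_f <- find_table(dir, "drug")
  reac_f <- find_table(dir, "reac")
  demo <- dplyr::distinct(need_cols(read_delim_table(demo_f, ","), "caseid", demo_f))
  drug <- need_cols(read_delim_table(drug_f, ","),
                    c("caseid", "drugname", "role"), drug_f)
  reac <- need_cols(read_delim_table(reac_f, ","), c("caseid", "pt"), reac_f)

  n_fail <- 0L
  sexl <- norm_label(col_or_na(demo, "sex"))
  cases <- tibble::tibble(
    report_id = demo$caseid,
    case_id = demo$caseid,
    version_key = demo$caseid,
    age = suppressWarnings(readr::parse_number(col_or_na(demo, "age"))),
    sex = dplyr::case_when(
      grepl("female|女", sexl) ~ "female",
      grepl("male|男", sexl) ~ "male",
      TRUE ~ "unknown"),
    weight = suppressWarnings(readr::parse_number(col_or_na(demo, "weight"))),
    event_year = suppressWarnings(as.integer(col_or_na(demo, "event_year"))),
    country = rep("JP", nrow(demo)),
    reporter = dplyr::coalesce(col_or_na(demo, "reporter"), "unknown"),
    outcomes = col_or_na(demo, "outcome")
  )
  sd <- parse_srs_date(col_or_na(drug, "start_date"))
  n_fail <- n_fail + attr(sd, "n_failed")
  drugs <- tibble::tibble(
    report_id = drug$caseid,
    verbatim_name = drug$drugname,
    ingredient = NA_character_,
    role = jader_role(drug$role),
    start_date = as.Date(sd),
    start_imputed = attr(sd, "imputed"),
    indication_pt = col_or_na(drug, "indication")
  )
  od <- parse_srs_date(col_or_na(reac, "onset_date"))
  n_fail <- n_fail + attr(od, "n_failed")
  events <- tibble::tibble(
    report_id = reac$caseid,
    pt = reac$pt,
    onset_date = as.Date(od),
    onset_imputed = attr(od, "imputed")
  )
  ds <- srs_dataset(cases, drugs, events, dialect = "jader")
  attr(ds, "n_date_failures") <- n_fail
  if (n_fail > 0) warn(sprintf("%d date field(s) could not be parsed and were set to NA", n_fail))
  ds
}

# -- CVAR -------------------------------------------------------------------

read_srs_cvar <- function(dir) {
  rep_f <- find_table(dir, "reports")
  drug_f <- find_table(dir, "report_drug")
  reac_f <- find_table(dir, "reactions")
  reports <- dplyr::distinct(need_cols(read_delim_table(rep_f, ","), "report_id", rep_f))
  drug <- need_cols(read_delim_table(drug_f, ","),
                    c("report_id", "drugname", "role"), drug_f)
  reac <- need_cols(read_delim_table(reac_f, ","), c("report_id", "pt"), reac_f)

  n_fail <- 0L
  sexl <- norm_label(col_or_na(reports, "sex"))
  cases <- tibble::tibble(
    report_id = reports$report_id,
    case_id = reports$report_id,
    version_key = reports$report_id,
    age = suppressWarnings(as.numeric(col_or_na(reports, "age"))),
    sex = dplyr::case_when(
      sexl == "female" | sexl == "f" ~ "female",
      sexl == "male" | sexl == "m" ~ "male",
      TRUE ~ "unknown"),
    weight = suppressWarnings(as.numeric(col_or_na(reports, "weight"))),
    event_year = suppressWarnings(as.integer(col_or_na(reports, "event_year"))),
    country = dplyr::coalesce(col_or_na(reports, "country"), "CA"),
    reporter = dplyr::coalesce(col_or_na(reports, "reporter"), "unknown"),
    outcomes = col_or_na(reports, "outcome")
  )
  rolel <- norm_label(drug$role)
  sd <- parse_srs_date(col_or_na(drug, "start_date"))
  n_fail <- n_fail + attr(sd, "n_failed")
  drugs <- tibble::tibble(
    report_id = drug$report_id,
    verbatim_name = drug$drugname,
    ingredient = NA_character_,
    role = dplyr::case_when(
      grepl("suspect", rolel) ~ "suspect",
      grepl("interact", rolel) ~ "interacting",
      grepl("concomitant|treatment", rolel) ~ "concomitant",
      TRUE ~ NA_character_),
    start_date = as.Date(sd),
    start_imputed = attr(sd, "imputed"),
    indication_pt = col_or_na(drug, "indication")
  )
  od <- parse_srs_date(col_or_na(reac, "onset_date"))
  n_fail <- n_fail + attr(od, "n_failed")
  events <- tibble::tibble(
    report_id = reac$report_id,
    pt = reac$pt,
    onset_date = as.Date(od),
    onset_imputed = attr(od, "imputed")
  )
  ds <- srs_dataset(cases, drugs, events, dialect = "cvar")
  attr(ds, "n_date_failures") <- n_fail
  if (n_fail > 0) warn(sprintf("%d date field(s) could not be parsed and were set to NA", n_fail))
  ds
}

# -- deduplication ----------------------------------------------------------

#' Deduplicate a spontaneous-report dataset
#'
#' FAERS (and synthetic) extracts keep one version per `case_id`: the
#' record with the greatest `version_key` (built from the FDA receipt
#' date and the report id), ties broken by the lexicographically greatest
#' `report_id` and logged. JADER and CVAR keep one case record per id.
#' Exact duplicate rows in the drug and event tables are dropped for all
#' dialects.
#'
#' The returned dataset carries a `dedup` attribute (see
#' [dedup_report()]) with the number of removed case versions, drug rows,
#' event rows and logged version-key ties. Deduplication is idempotent.
#'
#' @param ds an [srs_dataset()].
#' @return the deduplicated `srs_dataset`.
#' @export
deduplicate <- function(ds) {
  stopifnot(inherits(ds, "srs_dataset"))
  cases <- ds$cases
  n_ties <- 0L
  if (ds$dialect %in% c("faers", "synthetic")) {
    ord <- order(cases$case_id,
                 xtfrm(cases$version_key), xtfrm(cases$report_id),
                 decreasing = c(FALSE, TRUE, TRUE), method = "radix")
    sorted <- cases[ord, ]
    keep <- !duplicated(sorted$case_id)
    dup_next <- which(!keep)
    if (length(dup_next)) {
      prev <- dup_next - 1L
      n_ties <- sum(sorted$case_id[dup_next] == sorted$case_id[prev] &
                      sorted$version_key[dup_next] == sorted$version_key[prev])
      if (n_ties > 0) {
        warn(sprintf("%d version-key tie(s) resolved by greatest report_id", n_ties))
      }
    }
    kept <- sorted[keep, ]
  } else {
    kept <- cases[!duplicated(cases$case_id), ]
  }
  n_case_versions <- nrow(cases) - nrow(kept)
  drugs <- ds$drugs[ds$drugs$report_id %in% kept$report_id, ]
  events <- ds$events[ds$events$report_id %in% kept$report_id, ]
  drugs2 <- dplyr::distinct(drugs)
  events2 <- dplyr::distinct(events)
  out <- srs_dataset(dplyr::arrange(kept, .data$report_id), drugs2, events2,
                     dialect = ds$dialect)
  attr(out, "dedup") <- list(
    n_case_versions = n_case_versions,
    n_drug_rows = nrow(drugs) - nrow(drugs2),
    n_event_rows = nrow(events) - nrow(events2),
    n_ties = n_ties,
    n_removed = n_case_versions + (nrow(drugs) - nrow(drugs2)) +
      (nrow(events) - nrow(events2))
  )
  attr(out, "n_date_failures") <- attr(ds, "n_date_failures")
  out
}

#' @rdname deduplicate
#' @return `dedup_report()` returns the dedup bookkeeping list (or `NULL`
#'   for a dataset that has not been deduplicated).
#' @export
dedup_report <- function(ds) attr(ds, "dedup")

#' Assign canonical ingredients to drug records
#'
#' Every drug row whose verbatim name matches the dictionary
#' (case/whitespace/Unicode-insensitively) gets the canonical ingredient;
#' non-matching names keep `NA` and are retained.
#'
#' @param ds an [srs_dataset()].
#' @param dict a [drug_dictionary()].
#' @return the dataset with the `ingredient` column filled in.
#' @export
normalize_drugs <- function(ds, dict) {
  stopifnot(inherits(ds, "srs_dataset"))
  ds$drugs$ingredient <- dict_lookup(dict, ds$drugs$verbatim_name)
  ds
}

#' Report-level exposure and event sets
#'
#' Returns the sets of report ids exposed to any of the query ingredients
#' (under the dialect's role policy), reporting any of the query events,
#' and both. A report counts once regardless of duplicated drug or event
#' rows.
#'
#' @param ds an [srs_dataset()] (deduplicated and normalized).
#' @param ingredients character vector of canonical ingredients.
#' @param event_pts character vector of MedDRA preferred terms.
#' @param roles drug roles defining exposure; defaults to `"PS"` for
#'   FAERS/synthetic and `"suspect"` for JADER/CVAR.
#' @return list with sorted character vectors `exposed`, `with_event`,
#'   `both`.
#' @export
select_reports <- function(ds, ingredients, event_pts, roles = NULL) {
  stopifnot(inherits(ds, "srs_dataset"))
  if (length(ingredients) == 0) abort("ingredient set must be non-empty")
  if (length(event_pts) == 0) abort("event term set must be non-empty")
  roles <- roles %||% default_roles(ds$dialect)
  if (!all(roles %in% srs_roles)) abort("unknown role(s) in role policy")
  ing <- norm_label(ingredients)
  pts <- norm_label(event_pts)
  exposed <- ds$drugs |>
    dplyr::filter(!is.na(.data$ingredient),
                  norm_label(.data$ingredient) %in% ing,
                  .data$role %in% roles) |>
    dplyr::pull(.data$report_id) |>
    unique() |>
    sort()
  with_event <- ds$events |>
    dplyr::filter(norm_label(.data$pt) %in% pts) |>
    dplyr::pull(.data$report_id) |>
    unique() |>
    sort()
  list(exposed = exposed, with_event = with_event,
       both = intersect(exposed, with_event))
}

default_roles <- function(dialect) {
  switch(dialect,
    faers = "PS",
    synthetic = "PS",
    jader = "suspect",
    cvar = "suspect")
}
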