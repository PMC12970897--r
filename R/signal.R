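#' Signal-evaluation thresholds
#'
#' The joint four-algorithm criterion used throughout: a pair is a
#' positive signal when (1) the ROR 95% lower bound exceeds 1 with at
#' least `min_n` reports, (2) PRR exceeds 2 with Pearson chi-square of at
#' least 4, (3) IC025 exceeds 0, and (4) EBGM05 exceeds 2.
#'
#' @param min_n minimum case count (default 3).
#' @param ror_lower,prr,chi2,ic025,ebgm05 the four thresholds.
#' @return named list of thresholds.
#' @export
signal_thresholds <- function(min_n = 3, ror_lower = 1, prr = 2, chi2 = 4,
                              ic025 = 0, ebgm05 = 2) {
  list(min_n = min_n, ror_lower = ror_lower, prr = prr, chi2 = chi2,
       ic025 = ic025, ebgm05 = ebgm05)
}

#' Apply the joint signal criterion
#'
#' Adds the four per-algorithm flags and their conjunction to a signal
#' result row produced by [disproportionality()] or [signal_from_table()].
#'
#' @param r one-row signal-result tibble.
#' @param thresholds a [signal_thresholds()] list.
#' @return the row with `flag_ror`, `flag_prr`, `flag_ic`, `flag_ebgm`
#'   and `is_signal` set.
#' @export
evaluate_signal <- function(r, thresholds = signal_thresholds()) {
  th <- thresholds
  r$flag_ror <- r$ror_lower > th$ror_lower & r$n >= th$min_n
  r$flag_prr <- r$prr > th$prr & r$chi2 >= th$chi2
  r$flag_ic <- r$ic025 > th$ic025
  r$flag_ebgm <- r$ebgm05 > th$ebgm05
  r$is_signal <- r$flag_ror & r$flag_prr & r$flag_ic & r$flag_ebgm
  r
}

#' All four disproportionality statistics for one 2x2 table
#'
#' Computes ROR (with Wald CI), PRR (with CI and uncorrected Pearson
#' chi-square), the information component (raw by default; see
#' [information_component()]) and EBGM (unshrunk by default; pass a
#' fitted [gamma_poisson_prior()] for full MGPS shrinkage), then applies
#' the joint signal criterion.
#'
#' @param t a [contingency_table()].
#' @param prior optional `gamma_poisson_prior` for MGPS shrinkage.
#' @param ic_variant `"raw"` or `"shrunk"`.
#' @param haldane_correction continuity policy for zero cells.
#' @param thresholds a [signal_thresholds()] list.
#' @param n_mc,seed Monte-Carlo controls for `ic025_mc`.
#' @param label optional row label.
#' @return one-row tibble (class `signal_result`) with columns `n`,
#'   `ror`, `ror_lower`, `ror_upper`, `prr`, `prr_lower`, `prr_upper`,
#'   `chi2`, `E`, `rr`, `ic`, `ic025`, `ic025_mc`, `ebgm`, `ebgm05`,
#'   per-criterion flags and `is_signal`.
#' @export
signal_from_table <- function(t, prior = NULL, ic_variant = "raw",
                              haldane_correction = FALSE,
                              thresholds = signal_thresholds(),
                              n_mc = 1e4, seed = NULL, label = NA_character_) {
  rr_ci <- ror(t, haldane_correction)
  pr <- prr_chi2(t, haldane_correction)
  ec <- expected_count(t)
  # a zero a-cell has no raw IC; under the continuity policy fall back to
  # the credibility-shrunk variant instead of failing the whole row
  if (t$a == 0 && haldane_correction && ic_variant == "raw") {
    ic_variant <- "shrunk"
  }
  ic_res <- information_component(t$a, ec$E, variant = ic_variant,
                                  n_mc = n_mc, seed = seed)
  eb <- ebgm_score(t$a, ec$E, prior = prior)
  row <- tibble::tibble(
    label = label, n = t$a,
    ror = rr_ci$estimate, ror_lower = rr_ci$lower, ror_upper = rr_ci$upper,
    prr = pr$estimate, prr_lower = pr$lower, prr_upper = pr$upper,
    chi2 = pr$chi2,
    E = ec$E, rr = ec$rr,
    ic = ic_res$ic, ic025 = ic_res$ic025, ic025_mc = ic_res$ic025_mc,
    ebgm = eb$ebgm, ebgm05 = eb$ebgm05,
    corrected = rr_ci$corrected || pr$corrected
  )
  row <- evaluate_signal(row, thresholds)
  class(row) <- c("signal_result", class(row))
  row
}

#' Disproportionality analysis for a drug(-set) x event pair
#'
#' Builds the report-level 2x2 table with [build_table()] and returns
#' the full four-algorithm signal row.
#'
#' @inheritParams select_reports
#' @inheritParams signal_from_table
#' @return one-row `signal_result` tibble.
#' @export
disproportionality <- function(ds, ingredients, event_pts, roles = NULL,
                               prior = NULL, ic_variant = "raw",
                               haldane_correction = FALSE,
                               thresholds = signal_thresholds(),
                               n_mc = 1e4, seed = NULL,
                               label = paste(ingredients, collapse = "+")) {
  t <- build_table(ds, ingredients, event_pts, roles)
  signal_from_table(t, prior = prior, ic_variant = ic_variant,
                    haldane_correction = haldane_correction,
                    thresholds = thresholds, n_mc = n_mc, seed = seed,
                    label = label)
}

#' Restrict a dataset to a set of reports
#'
#' Keeps only the given report ids in all three tables; the complement
#' of the set is removed from the background as well, so downstream
#' contingency tables treat the restriction as a complete database.
#'
#' @param ds an [srs_dataset()].
#' @param report_ids character vector of report ids to keep.
#' @return the restricted `srs_dataset`.
#' @export
filter_reports <- function(ds, report_ids) {
  srs_dataset(
    cases = ds$cases[ds$cases$report_id %in% report_ids, ],
    drugs = ds$drugs[ds$drugs$report_id %in% report_ids, ],
    events = ds$events[ds$events$report_id %in% report_ids, ],
    dialect = ds$dialect
  )
}

not_evaluable_row <- function(label, level, reason) {
  tibble::tibble(label = label, level = level, evaluable = FALSE,
                 reason = reason)
}

#' Subgroup disproportionality analysis
#'
#' Stratifies the whole database by age (`< cut` vs `>= cut`, default
#' 65 years), sex (female vs male) or indication of the index drug
#' (asthma vs other indications), and analyzes each stratum as its own
#' complete database: all four 2x2 cells are recomputed within the
#' stratum. Reports with a missing stratum value are excluded from that
#' axis. Strata in which the table is degenerate (e.g. no drug-event
#' reports) are returned as non-evaluable rows.
#'
#' @inheritParams disproportionality
#' @param axis `"age"`, `"sex"` or `"indication"`.
#' @param age_cut age cutpoint in years (default 65).
#' @return tibble with one row per stratum (`level` column), the signal
#'   statistics where evaluable.
#' @export
subgroup_analysis <- function(ds, ingredients, event_pts,
                              axis = c("age", "sex", "indication"),
                              roles = NULL, age_cut = 65, ...) {
  axis <- match.arg(axis)
  label <- paste(ingredients, collapse = "+")
  strata <- switch(axis,
    age = {
      ok <- !is.na(ds$cases$age)
      split(ds$cases$report_id[ok],
            ifelse(ds$cases$age[ok] < age_cut,
                   paste0("<", age_cut), paste0(">=", age_cut)))
    },
    sex = {
      ok <- ds$cases$sex %in% c("female", "male")
      split(ds$cases$report_id[ok], ds$cases$sex[ok])
    },
    indication = {
      idx <- ds$drugs |>
        dplyr::filter(!is.na(.data$ingredient),
                      norm_label(.data$ingredient) %in% norm_label(ingredients),
                      !is.na(.data$indication_pt)) |>
        dplyr::mutate(asthma = stringr::str_detect(norm_label(.data$indication_pt),
                                                   "asthma")) |>
        dplyr::group_by(.data$report_id) |>
        dplyr::summarise(level = ifelse(any(.data$asthma), "asthma", "others"))
      # reports without the index drug keep their background role in both strata?
      # No: each stratum is index-drug reports of that indication plus all
      # reports without the index drug (shared background).
      exposed_all <- ds$drugs |>
        dplyr::filter(!is.na(.data$ingredient),
                      norm_label(.data$ingredient) %in% norm_label(ingredients)) |>
        dplyr::pull(.data$report_id) |>
        unique()
      background <- setdiff(ds$cases$report_id, exposed_all)
      list(
        asthma = c(idx$report_id[idx$level == "asthma"], background),
        others = c(idx$report_id[idx$level == "others"], background)
      )
    }
  )
  purrr::map_dfr(names(strata), function(lev) {
    sub <- filter_reports(ds, strata[[lev]])
    res <- tryCatch(
      disproportionality(sub, ingredients, event_pts, roles = roles,
                         label = label, ...),
      error = function(e) not_evaluable_row(label, lev, conditionMessage(e))
    )
    if (!"level" %in% names(res)) {
      res$level <- lev
      res$evaluable <- TRUE
      res$reason <- NA_character_
    }
    res
  }) |>
    dplyr::relocate("label", "level")
}

#' Co-medication disproportionality analysis
#'
#' `mode = "require"` restricts the whole database to reports listing
#' the co-medication (any role) before building the 2x2 table;
#' `mode = "exclude"` removes such reports from the whole database. The
#' full four-algorithm analysis then runs on the restricted database.
#'
#' @inheritParams disproportionality
#' @param ingredient the index drug (single ingredient).
#' @param comed the co-medication ingredient.
#' @param mode `"require"` or `"exclude"`.
#' @return one-row `signal_result` tibble.
#' @export
comedication_analysis <- function(ds, ingredient, event_pts, comed,
                                  mode = c("require", "exclude"),
                                  roles = NULL, ...) {
  mode <- match.arg(mode)
  with_comed <- ds$drugs |>
    dplyr::filter(!is.na(.data$ingredient),
                  norm_label(.data$ingredient) == norm_label(comed)) |>
    dplyr::pull(.data$report_id) |>
    unique()
  keep <- switch(mode,
    require = with_comed,
    exclude = setdiff(ds$cases$report_id, with_comed))
  if (length(keep) == 0) abort("restricted database is empty")
  sub <- filter_reports(ds, keep)
  disproportionality(sub, ingredient, event_pts, roles = roles,
                     label = sprintf("%s [%s %s]", ingredient, mode, comed),
                     ...)
}

#' Most frequent co-medications among drug-event reports
#'
#' Counts, among reports carrying the index drug and the target event,
#' the distinct co-reported ingredients (any role), one count per report.
#' Ties are broken alphabetically.
#'
#' @inheritParams comedication_analysis
#' @param k number of top co-medications to return.
#' @return tibble with `ingredient` and `n_reports`, descending.
#' @export
top_comedications <- function(ds, ingredient, event_pts, k = 10, roles = NULL) {
  if (k < 1) abort("k must be >= 1")
  sets <- select_reports(ds, ingredient, event_pts, roles)
  index_norm <- norm_label(ingredient)
  ds$drugs |>
    dplyr::filter(.data$report_id %in% sets$both,
                  !is.na(.data$ingredient),
                  norm_label(.data$ingredient) != index_norm) |>
    dplyr::distinct(.data$report_id, .data$ingredient) |>
    dplyr::count(.data$ingredient, name = "n_reports") |>
    dplyr::arrange(dplyr::desc(.data$n_reports), .data$ingredient) |>
    utils::head(k)
}
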