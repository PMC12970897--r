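#' Configuration for the synthetic report generator
#'
#' Defines a synthetic spontaneous-reporting database with known ground
#' truth. Drug exposures are independent Bernoulli draws per report;
#' each event's baseline probability is multiplied by `target_rr` when
#' its paired signal drug is present, which gives closed-form expected
#' 2x2 cells. One present drug per report is assigned the PS role
#' uniformly at random; the rest are concomitant. Time-to-onset for
#' signal pairs is drawn from a Weibull distribution with the pair's
#' scale/shape; duplicates are injected as re-versioned copies of
#' existing cases; missingness is applied completely at random.
#'
#' The defaults emulate a FAERS-like background: leukotriene receptor
#' antagonists at realistic exposure frequencies, an EGPA-like rare
#' event, the montelukast pair planted with the relative reporting rate
#' and Weibull onset profile observed for that association
#' (`rr = 180`, scale 391 days, shape 0.76), plus common co-medications
#' and background events.
#'
#' @param n_reports number of case reports before duplicate injection.
#' @param drugs tibble with `ingredient`, `p_exposure`.
#' @param events tibble with `pt`, `p_base`.
#' @param signals tibble with `ingredient`, `event_pt`, `target_rr`,
#'   `tto_scale` (days), `tto_shape`.
#' @param duplicate_rate fraction of cases duplicated as newer versions.
#' @param missingness named list of MCAR missingness rates for `age`,
#'   `weight`, `sex`, `country`, `start_date`, `onset_date`,
#'   `indication`.
#' @param name_variants named list: ingredient -> extra verbatim
#'   spellings (trade names) the generator may emit.
#' @param seed RNG seed; the same config generates byte-identical data.
#' @return a `generator_config` list.
#' @export
generator_config <- function(
    n_reports = 200000,
    drugs = default_drug_vocab(),
    events = default_event_vocab(),
    signals = default_signals(),
    duplicate_rate = 0.05,
    missingness = list(age = 0.15, weight = 0.35, sex = 0.03, country = 0.1,
                       start_date = 0.35, onset_date = 0.35, indication = 0.25),
    name_variants = default_name_variants(),
    seed = 1) {
  drugs <- tibble::as_tibble(drugs)
  events <- tibble::as_tibble(events)
  signals <- tibble::as_tibble(signals)
  stopifnot(nrow(drugs) > 0, nrow(events) > 0,
            all(drugs$p_exposure >= 0 & drugs$p_exposure <= 1),
            all(events$p_base >= 0 & events$p_base <= 1))
  if (nrow(signals)) {
    stopifnot(all(signals$target_rr >= 0), all(signals$tto_scale > 0),
              all(signals$tto_shape > 0),
              all(signals$ingredient %in% drugs$ingredient),
              all(signals$event_pt %in% events$pt))
  }
  stopifnot(duplicate_rate >= 0, duplicate_rate <= 1)
  structure(list(n_reports = n_reports, drugs = drugs, events = events,
                 signals = signals, duplicate_rate = duplicate_rate,
                 missingness = missingness, name_variants = name_variants,
                 seed = seed),
            class = "generator_config")
}

#' @rdname generator_config
#' @export
default_drug_vocab <- function() {
  tibble::tribble(
    ~ingredient, ~p_exposure,
    "montelukast", 0.002,
    "zafirlukast", 0.0005,
    "pranlukast", 0.0005,
    "ibudilast", 0.0002,
    "prednisone", 0.012,
    "fluticasone", 0.010,
    "budesonide", 0.008,
    "salmeterol", 0.006,
    "aspirin", 0.02,
    "paracetamol", 0.025
  )
}

#' @rdname generator_config
#' @export
default_event_vocab <- function() {
  tibble::tribble(
    ~pt, ~p_base,
    "Eosinophilic granulomatosis with polyangiitis", 3e-05,
    "Churg-Strauss syndrome", 1.5e-05,
    "Headache", 0.02,
    "Nausea", 0.015,
    "Dyspnoea", 0.012,
    "Rash", 0.01,
    "Insomnia", 0.008
  )
}

#' @rdname generator_config
#' @export
default_signals <- function() {
  tibble::tribble(
    ~ingredient, ~event_pt, ~target_rr, ~tto_scale, ~tto_shape,
    "montelukast", "Eosinophilic granulomatosis with polyangiitis", 180, 391.08, 0.76,
    "pranlukast", "Eosinophilic granulomatosis with polyangiitis", 180, 254.86, 0.75
  )
}

default_name_variants <- function() {
  list(
    montelukast = c("SINGULAIR", "Montelukast sodium"),
    zafirlukast = c("ACCOLATE"),
    pranlukast = c("ONON", "Pranlukast hydrate"),
    ibudilast = c("KETAS")
  )
}

#' Generate a synthetic spontaneous-reporting dataset
#'
#' See [generator_config()] for the generative model. Returns the
#' dataset (dialect `"synthetic"`, FAERS-style case versioning so that
#' [deduplicate()] recovers exactly the injected duplicates) together
#' with ground-truth tables.
#'
#' @param cfg a [generator_config()].
#' @return list with elements
#'   * `dataset` — the [srs_dataset()] (drug names verbatim; run
#'     [normalize_drugs()] with `dictionary`);
#'   * `dictionary` — a [drug_dictionary()] covering the vocabulary and
#'     its name variants;
#'   * `truth` — list with `pairs` (realized and expected 2x2 cells per
#'     signal pair, presence-level), `tto` (per-report sampled
#'     time-to-onset for signal pairs, with an `observable` flag),
#'     `n_duplicates`, and the realized exposure/event marginals.
#' @export
generate_srs <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed, generate_srs_impl(cfg))
}

generate_srs_impl <- function(cfg) {
  n <- cfg$n_reports
  nd <- nrow(cfg$drugs)
  ne <- nrow(cfg$events)

  # exposures and events -----------------------------------------------------
  X <- matrix(runif(n * nd), n, nd) < rep(cfg$drugs$p_exposure, each = n)
  P <- matrix(rep(cfg$events$p_base, each = n), n, ne)
  if (nrow(cfg$signals)) {
    for (s in seq_len(nrow(cfg$signals))) {
      k <- match(cfg$signals$ingredient[s], cfg$drugs$ingredient)
      j <- match(cfg$signals$event_pt[s], cfg$events$pt)
      P[X[, k], j] <- P[X[, k], j] * cfg$signals$target_rr[s]
      exp_a <- n * cfg$drugs$p_exposure[k] *
        min(1, cfg$events$p_base[j] * cfg$signals$target_rr[s])
      if (exp_a < 1) {
        warn(sprintf("expected co-report count for %s x %s is %.2f (< 1)",
                     cfg$signals$ingredient[s], cfg$signals$event_pt[s], exp_a))
      }
    }
  }
  P <- pmin(P, 1)
  Y <- matrix(runif(n * ne), n, ne) < P

  # case table ---------------------------------------------------------------
  case_id <- sprintf("C%07d", seq_len(n))
  report_id <- paste0(case_id, "-1")
  fda_dt <- as.Date("2004-01-01") + floor(runif(n) * 7670)
  mix <- runif(n)
  age <- ifelse(mix < 0.12, runif(n, 5, 18),
                ifelse(mix < 0.78, rnorm(n, 46, 14), rnorm(n, 74, 6)))
  age <- pmax(age, 0)
  sex <- sample(c("female", "male", "unknown"), n, TRUE, c(0.54, 0.44, 0.02))
  weight <- rlnorm(n, log(72), 0.22)
  reporter <- sample(c("physician", "pharmacist", "other health professional",
                       "non-health professional", "unknown"),
                     n, TRUE, c(0.35, 0.12, 0.18, 0.25, 0.10))
  country <- sample(c("US", "GB", "JP", "CA", "FR", "DE"), n, TRUE,
                    c(0.45, 0.12, 0.12, 0.10, 0.11, 0.10))
  outcomes <- sample(c(NA, "hospitalization", "other", "death",
                       "life-threatening", "disability"),
                     n, TRUE, c(0.40, 0.25, 0.20, 0.05, 0.05, 0.05))
  m <- cfg$missingness
  age[runif(n) < (m$age %||% 0)] <- NA
  weight[runif(n) < (m$weight %||% 0)] <- NA
  sex[runif(n) < (m$sex %||% 0)] <- "unknown"
  country[runif(n) < (m$country %||% 0)] <- NA
  cases <- tibble::tibble(
    report_id = report_id, case_id = case_id,
    version_key = paste0(format(fda_dt, "%Y%m%d"), "#", pad_key(report_id)),
    age = age, sex = sex, weight = weight,
    event_year = as.integer(format(fda_dt, "%Y")),
    country = country, reporter = reporter, outcomes = outcomes
  )

  # drug table ---------------------------------------------------------------
  ij <- which(X, arr.ind = TRUE)
  d_report <- ij[, 1]
  d_drug <- ij[, 2]
  u <- runif(length(d_report))
  is_ps <- u == stats::ave(u, d_report, FUN = max)
  ingredient <- cfg$drugs$ingredient[d_drug]
  verbatim <- vapply(ingredient, function(g) {
    vars <- c(g, toupper(g), cfg$name_variants[[g]])
    vars[[sample.int(length(vars), 1)]]
  }, "")
  start <- fda_dt[d_report] - floor(runif(length(d_report), 30, 1000))
  indications <- c("Asthma", "Rhinitis", "Hypersensitivity", "Hypertension",
                   "Chronic obstructive pulmonary disease")
  indi <- sample(indications, length(d_report), TRUE,
                 c(0.6, 0.15, 0.08, 0.09, 0.08))
  indi[runif(length(d_report)) < (m$indication %||% 0)] <- NA
  # start-date lookup key per (report, drug) for onset construction
  start_key <- (d_drug - 1) * n + d_report

  # event table --------------------------------------------------------------
  ev <- which(Y, arr.ind = TRUE)
  e_report <- ev[, 1]
  e_event <- ev[, 2]
  onset <- fda_dt[e_report] - floor(runif(length(e_report), 0, 365))
  start_missing <- runif(length(d_report)) < (m$start_date %||% 0)
  onset_missing <- runif(length(e_report)) < (m$onset_date %||% 0)
  tto_truth <- NULL
  if (nrow(cfg$signals)) {
    assigned <- rep(FALSE, length(e_report))
    for (s in seq_len(nrow(cfg$signals))) {
      k <- match(cfg$signals$ingredient[s], cfg$drugs$ingredient)
      j <- match(cfg$signals$event_pt[s], cfg$events$pt)
      hit <- which(!assigned & e_event == j & X[cbind(e_report, k)])
      if (!length(hit)) next
      tto <- rweibull(length(hit), shape = cfg$signals$tto_shape[s],
                      scale = cfg$signals$tto_scale[s])
      tto <- pmax(tto, 0.5)  # same-day onsets recorded as day intervals >= 1
      drow <- match((k - 1) * n + e_report[hit], start_key)
      onset[hit] <- start[drow] + ceiling(tto)
      assigned[hit] <- TRUE
      tto_truth <- dplyr::bind_rows(tto_truth, tibble::tibble(
        report_id = report_id[e_report[hit]],
        ingredient = cfg$signals$ingredient[s],
        pt = cfg$signals$event_pt[s],
        tto_days = as.numeric(ceiling(tto)),
        observable = !start_missing[drow] & !onset_missing[hit]
      ))
    }
  }
  start[start_missing] <- NA
  onset[onset_missing] <- NA

  drugs <- tibble::tibble(
    report_id = report_id[d_report],
    verbatim_name = unname(verbatim),
    ingredient = NA_character_,
    role = ifelse(is_ps, "PS", "concomitant"),
    start_date = start, start_imputed = FALSE,
    indication_pt = indi
  )
  events <- tibble::tibble(
    report_id = report_id[e_report],
    pt = cfg$events$pt[e_event],
    onset_date = onset, onset_imputed = FALSE
  )

  # duplicate injection ------------------------------------------------------
  n_dup <- round(cfg$duplicate_rate * n)
  if (n_dup > 0) {
    pick <- sample.int(n, n_dup)
    dup_report <- paste0(case_id[pick], "-2")
    dup_dt <- fda_dt[pick] + floor(runif(n_dup, 30, 400))
    dup_cases <- cases[pick, ]
    dup_cases$report_id <- dup_report
    dup_cases$version_key <- paste0(format(dup_dt, "%Y%m%d"), "#",
                                    pad_key(dup_report))
    remap <- setNames(dup_report, report_id[pick])
    dup_drugs <- drugs[drugs$report_id %in% report_id[pick], ]
    dup_drugs$report_id <- unname(remap[dup_drugs$report_id])
    dup_events <- events[events$report_id %in% report_id[pick], ]
    dup_events$report_id <- unname(remap[dup_events$report_id])
    cases <- dplyr::bind_rows(cases, dup_cases)
    drugs <- dplyr::bind_rows(drugs, dup_drugs)
    events <- dplyr::bind_rows(events, dup_events)
  }

  # ground truth -------------------------------------------------------------
  pairs <- NULL
  if (nrow(cfg$signals)) {
    pairs <- purrr::map_dfr(seq_len(nrow(cfg$signals)), function(s) {
      k <- match(cfg$signals$ingredient[s], cfg$drugs$ingredient)
      j <- match(cfg$signals$event_pt[s], cfg$events$pt)
      a <- sum(X[, k] & Y[, j])
      p_e <- cfg$drugs$p_exposure[k]
      p_ev1 <- min(1, cfg$events$p_base[j] * cfg$signals$target_rr[s])
      p_ev0 <- cfg$events$p_base[j]
      tibble::tibble(
        ingredient = cfg$signals$ingredient[s],
        event_pt = cfg$signals$event_pt[s],
        target_rr = cfg$signals$target_rr[s],
        a = a, b = sum(X[, k]) - a, c = sum(Y[, j]) - a,
        d = n - sum(X[, k]) - sum(Y[, j]) + a,
        expected_a = n * p_e * p_ev1,
        expected_b = n * p_e * (1 - p_ev1),
        expected_c = n * (1 - p_e) * p_ev0,
        expected_d = n * (1 - p_e) * (1 - p_ev0)
      )
    })
  }
  truth <- list(
    pairs = pairs,
    tto = tto_truth,
    n_duplicates = n_dup,
    exposure_freq = tibble::tibble(ingredient = cfg$drugs$ingredient,
                                   p_exposure = cfg$drugs$p_exposure,
                                   observed = colMeans(X)),
    event_freq = tibble::tibble(pt = cfg$events$pt,
                                p_base = cfg$events$p_base,
                                observed = colMeans(Y))
  )
  dict_tab <- purrr::map_dfr(cfg$drugs$ingredient, function(g) {
    tibble::tibble(name = c(g, cfg$name_variants[[g]]), ingredient = g)
  })
  list(
    dataset = srs_dataset(cases, drugs, events, dialect = "synthetic"),
    dictionary = drug_dictionary(dict_tab),
    truth = truth
  )
}
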