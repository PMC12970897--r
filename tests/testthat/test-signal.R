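test_that("the joint criterion fires on the published row and gates small n", {
  t <- reconstruct_table(822, 104037, 2509, 268.58)
  r <- signal_from_table(t, seed = 1)
  expect_true(all(r$flag_ror, r$flag_prr, r$flag_ic, r$flag_ebgm))
  expect_true(r$is_signal)
  # enormous ROR but only 2 cases: case-count gate blocks the signal
  t2 <- contingency_table(2, 1, 1, 10000)
  r2 <- signal_from_table(t2, seed = 1)
  expect_gt(r2$ror, 1000)
  expect_false(r2$flag_ror)
  expect_false(r2$is_signal)
})

test_that("strata of identical composition give identical results", {
  base <- toy_dataset(12, 30, 40, 400)
  young <- base; old <- base
  young$cases$age <- 40
  old$cases$age <- 75
  old$cases$report_id <- paste0("O", old$cases$report_id)
  old$cases$case_id <- old$cases$report_id
  old$cases$version_key <- old$cases$report_id
  old$drugs$report_id <- paste0("O", old$drugs$report_id)
  old$events$report_id <- paste0("O", old$events$report_id)
  ds <- srs_dataset(dplyr::bind_rows(young$cases, old$cases),
                    dplyr::bind_rows(young$drugs, old$drugs),
                    dplyr::bind_rows(young$events, old$events), "synthetic")
  out <- subgroup_analysis(ds, "drugx", "Event of interest", axis = "age",
                           seed = 1)
  expect_equal(nrow(out), 2)
  num <- c("n", "ror", "ror_lower", "prr", "chi2", "ic", "ic025", "ebgm", "ebgm05")
  expect_equal(out[1, num], out[2, num])
})

test_that("planted age heterogeneity is detected only in the right stratum", {
  # <65: null composition; >=65: strong excess of drug-event reports
  young <- toy_dataset(2, 198, 200, 19600)   # RR ~ 1
  old <- toy_dataset(60, 140, 140, 19660)    # strong signal
  young$cases$age <- 40; old$cases$age <- 75
  old$cases$report_id <- paste0("O", old$cases$report_id)
  old$cases$case_id <- old$cases$report_id
  old$cases$version_key <- old$cases$report_id
  old$drugs$report_id <- paste0("O", old$drugs$report_id)
  old$events$report_id <- paste0("O", old$events$report_id)
  ds <- srs_dataset(dplyr::bind_rows(young$cases, old$cases),
                    dplyr::bind_rows(young$drugs, old$drugs),
                    dplyr::bind_rows(young$events, old$events), "synthetic")
  out <- subgroup_analysis(ds, "drugx", "Event of interest", axis = "age",
                           seed = 1)
  expect_true(out$is_signal[out$level == ">=65"])
  expect_false(out$is_signal[out$level == "<65"])
})

test_that("indication subgroups split index-drug reports, sharing background", {
  ds <- toy_dataset(20, 80, 50, 850)
  idx <- ds$drugs$report_id
  ds$drugs$indication_pt <- rep(c("Asthma", "Rhinitis"), length.out = length(idx))
  out <- subgroup_analysis(ds, "drugx", "Event of interest",
                           axis = "indication", seed = 1)
  expect_setequal(out$level, c("asthma", "others"))
  # exposed reports split across strata; a_asthma + a_others = overall a
  expect_equal(sum(out$n), 20)
})

test_that("non-evaluable strata are reported instead of erroring", {
  ds <- toy_dataset(5, 20, 20, 200)
  ds$cases$sex <- rep(c("female", "male"), length.out = n_reports(ds))
  # remove every drug-event pair from the male stratum
  both <- select_reports(ds, "drugx", "Event of interest")$both
  ds$cases$sex[ds$cases$report_id %in% both] <- "female"
  ds$cases$sex[1] <- "female"
  out <- subgroup_analysis(ds, "drugx", "Event of interest", axis = "sex",
                           seed = 1)
  expect_true(all(c("female", "male") %in% out$level))
  male <- out[out$level == "male", ]
  expect_false(isTRUE(male$evaluable))
})

test_that("co-medication require/exclude reduce to the unrestricted analysis", {
  ds <- toy_dataset(10, 40, 30, 420)
  # comed absent from the data: exclude changes nothing
  full <- disproportionality(ds, "drugx", "Event of interest", seed = 1)
  excl <- comedication_analysis(ds, "drugx", "Event of interest",
                                comed = "notpresent", mode = "exclude", seed = 1)
  num <- c("n", "ror", "prr", "chi2", "ic", "ebgm")
  expect_equal(as.list(excl[num]), as.list(full[num]))
  # comed on every report: require changes nothing
  ds2 <- ds
  ds2$drugs <- dplyr::bind_rows(ds2$drugs, tibble::tibble(
    report_id = ds2$cases$report_id, verbatim_name = "ubiquitol",
    ingredient = "ubiquitol", role = "concomitant"))
  req <- comedication_analysis(ds2, "drugx", "Event of interest",
                               comed = "ubiquitol", mode = "require", seed = 1)
  full2 <- disproportionality(ds2, "drugx", "Event of interest", seed = 1)
  expect_equal(as.list(req[num]), as.list(full2[num]))
  expect_error(comedication_analysis(ds, "drugx", "Event of interest",
                                     comed = "notpresent", mode = "require"),
               "empty")
})

test_that("excluding a confounding co-medication removes the planted signal", {
  set.seed(51)
  n <- 20000
  ids <- sprintf("R%05d", 1:n)
  comed <- runif(n) < 0.10
  drug <- ifelse(comed, runif(n) < 0.40, runif(n) < 0.01)
  # event depends only on the comed
  event <- ifelse(comed, runif(n) < 0.10, runif(n) < 0.002)
  cases <- tibble::tibble(report_id = ids, case_id = ids, version_key = ids)
  drugs <- dplyr::bind_rows(
    tibble::tibble(report_id = ids[drug], verbatim_name = "indexdrug",
                   ingredient = "indexdrug", role = "PS"),
    tibble::tibble(report_id = ids[comed], verbatim_name = "steroid",
                   ingredient = "steroid", role = "concomitant"))
  events <- tibble::tibble(report_id = ids[event], pt = "Planted event")
  ds <- srs_dataset(cases, drugs, events, "synthetic")
  naive <- disproportionality(ds, "indexdrug", "Planted event",
                              haldane_correction = TRUE, seed = 1)
  expect_true(naive$is_signal)
  cleaned <- comedication_analysis(ds, "indexdrug", "Planted event",
                                   comed = "steroid", mode = "exclude",
                                   haldane_correction = TRUE, seed = 1)
  expect_false(cleaned$is_signal)
})

test_that("top co-medications count reports once and break ties by name", {
  ds <- toy_dataset(1, 0, 0, 3, drug = "indexdrug", pt = "Evt")
  both_id <- select_reports(ds, "indexdrug", "Evt")$both
  ds$drugs <- dplyr::bind_rows(ds$drugs, tibble::tibble(
    report_id = both_id,
    verbatim_name = c("zeta", "alpha", "alpha"),
    ingredient = c("zeta", "alpha", "alpha"), role = "concomitant"))
  top <- top_comedications(ds, "indexdrug", "Evt", k = 10)
  expect_equal(top$ingredient, c("alpha", "zeta"))  # tie broken alphabetically
  expect_equal(top$n_reports, c(1, 1))              # duplicated row counts once
  expect_equal(nrow(top_comedications(ds, "indexdrug", "Evt", k = 1)), 1)
})

test_that("top co-medications equal exhaustive counting on synthetic data", {
  sim <- generate_srs(generator_config(
    n_reports = 3000, duplicate_rate = 0,
    drugs = tibble::tibble(ingredient = c("idx", "x1", "x2", "x3"),
                           p_exposure = c(0.1, 0.15, 0.1, 0.05)),
    events = tibble::tibble(pt = "Evt", p_base = 0.2),
    signals = tibble::tibble(ingredient = "idx", event_pt = "Evt",
                             target_rr = 2, tto_scale = 50, tto_shape = 1),
    seed = 8))
  ds <- normalize_drugs(sim$dataset, sim$dictionary)
  top <- top_comedications(ds, "idx", "Evt", k = 10, roles = srs_roles_all())
  both <- select_reports(ds, "idx", "Evt", roles = srs_roles_all())$both
  for (g in top$ingredient) {
    brute <- sum(vapply(both, function(id) {
      any(ds$drugs$ingredient[ds$drugs$report_id == id] %in% g)
    }, TRUE))
    expect_equal(top$n_reports[top$ingredient == g], brute)
  }
})
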