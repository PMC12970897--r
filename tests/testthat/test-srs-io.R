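test_that("FAERS dialect parses demographics, roles, dates and outcomes", {
  dir <- write_faers_fixture()
  ds <- read_srs(dir, "faers")
  expect_s3_class(ds, "srs_dataset")
  expect_equal(n_reports(ds), 4)
  expect_setequal(ds$cases$case_id, c("C1", "C1", "C2", "C3"))
  c1 <- ds$cases[ds$cases$report_id == "1001", ]
  expect_equal(c1$sex, "female")
  expect_equal(c1$age, 45)
  expect_equal(c1$reporter, "physician")
  # outcomes collected per report, sorted and joined
  expect_equal(ds$cases$outcomes[ds$cases$report_id == "1002"],
               "hospitalization;other")
  # therapy start joined by drug_seq; partial date imputed to the 1st
  d3001 <- ds$drugs[ds$drugs$report_id == "3001", ]
  expect_equal(d3001$start_date, as.Date("2023-03-01"))
  expect_true(d3001$start_imputed)
  expect_equal(d3001$indication_pt, "Rhinitis")
  expect_equal(unique(ds$drugs$role[ds$drugs$verbatim_name == "PREDNISONE"]),
               "concomitant")
})

test_that("a DEMO fixture with duplicate rows yields one case per primaryid", {
  dir <- withr::local_tempdir()
  writeLines(c("primaryid$caseid$fda_dt",
               "10$A$20230101",
               "20$B$20230202",
               "20$B$20230202"), file.path(dir, "DEMO.txt"))
  writeLines(c("primaryid$drugname$role_cod", "10$aspirin$PS"),
             file.path(dir, "DRUG.txt"))
  writeLines(c("primaryid$pt", "10$Rash"), file.path(dir, "REAC.txt"))
  ds <- read_srs(dir, "faers")
  expect_equal(n_reports(ds), 2)
})

test_that("missing mandatory columns are reported with file and column", {
  dir <- withr::local_tempdir()
  writeLines(c("primaryid$fda_dt", "10$20230101"), file.path(dir, "DEMO.txt"))
  writeLines(c("primaryid$drugname$role_cod", "10$aspirin$PS"),
             file.path(dir, "DRUG.txt"))
  writeLines(c("primaryid$pt", "10$Rash"), file.path(dir, "REAC.txt"))
  expect_error(read_srs(dir, "faers"), "DEMO.*caseid")
})

test_that("drug rows referencing unknown report ids raise an orphan error", {
  dir <- write_cvar_fixture(orphan = TRUE)
  expect_error(read_srs(dir, "cvar"), "V9")
})

test_that("JADER exact duplicate drug rows collapse to one after dedup", {
  dir <- write_jader_fixture()
  ds <- deduplicate(read_srs(dir, "jader"))
  j1 <- ds$drugs[ds$drugs$report_id == "J1", ]
  expect_equal(nrow(j1), 1)
  expect_equal(dedup_report(ds)$n_drug_rows, 1)
})

test_that("partial and unparseable dates are imputed or nulled with a count", {
  d <- parse_srs_date(c("20200131", "2020-01-31", "202003", "2021", "31-XY", NA))
  expect_equal(as.Date(d)[1:4],
               as.Date(c("2020-01-31", "2020-01-31", "2020-03-01", "2021-01-01")))
  expect_equal(attr(d, "imputed")[1:4], c(FALSE, FALSE, TRUE, TRUE))
  expect_true(is.na(as.Date(d)[5]) && is.na(as.Date(d)[6]))
  expect_equal(attr(d, "n_failed"), 1)
})

test_that("FAERS dedup keeps the greatest version per case and is idempotent", {
  dir <- write_faers_fixture()
  ds <- deduplicate(read_srs(dir, "faers"))
  # case C1 has versions 1001 (fda_dt 20230101) and 1002 (20240101)
  expect_false("1001" %in% ds$cases$report_id)
  expect_true("1002" %in% ds$cases$report_id)
  expect_equal(dedup_report(ds)$n_case_versions, 1)
  again <- deduplicate(ds)
  expect_equal(dedup_report(again)$n_removed, 0)
  expect_equal(again$cases, ds$cases)
  expect_equal(again$drugs, ds$drugs)
})

test_that("version-key ties resolve to the greatest report_id with a warning", {
  cases <- tibble::tibble(report_id = c("9", "8"), case_id = c("K", "K"),
                          version_key = c("20240101#9", "20240101#9"))
  ds <- srs_dataset(cases, tibble::tibble(report_id = character()),
                    tibble::tibble(report_id = character()), "faers")
  expect_warning(out <- deduplicate(ds), "tie")
  expect_equal(out$cases$report_id, "9")
})

test_that("drug-name normalization matches trade names case-insensitively", {
  dir <- write_faers_fixture()
  ds <- normalize_drugs(deduplicate(read_srs(dir, "faers")), ltra_dictionary())
  expect_equal(ds$drugs$ingredient[ds$drugs$verbatim_name == "SINGULAIR"],
               "montelukast")
  expect_equal(ds$drugs$ingredient[ds$drugs$verbatim_name == "Montelukast Sodium"],
               "montelukast")
  # unmatched names retained with NA ingredient
  expect_true(is.na(ds$drugs$ingredient[ds$drugs$verbatim_name == "PREDNISONE"]))
  expect_equal(dict_lookup(ltra_dictionary(), " montelukast  "), "montelukast")
})

test_that("select_reports honours role policy and counts a report once", {
  cases <- tibble::tibble(report_id = c("r1", "r2"), case_id = c("r1", "r2"),
                          version_key = c("r1", "r2"))
  drugs <- tibble::tibble(
    report_id = c("r1", "r1", "r2"),
    verbatim_name = "x", ingredient = "montelukast",
    role = c("PS", "PS", "concomitant"))
  events <- tibble::tibble(report_id = c("r1", "r1", "r2"),
                           pt = c("EGPA evt", "EGPA evt", "EGPA evt"))
  ds <- srs_dataset(cases, drugs, events, "faers")
  sets <- select_reports(ds, "montelukast", "EGPA evt")
  expect_equal(sets$exposed, "r1")       # r2 concomitant-only excluded
  expect_equal(sets$with_event, c("r1", "r2"))
  expect_equal(sets$both, "r1")          # duplicate rows count once
  expect_error(select_reports(ds, character(0), "EGPA evt"), "non-empty")
})

test_that("select_reports agrees with an exhaustive per-report scan", {
  sim <- generate_srs(generator_config(
    n_reports = 400, duplicate_rate = 0,
    drugs = tibble::tibble(ingredient = c("a_drug", "b_drug"),
                           p_exposure = c(0.3, 0.2)),
    events = tibble::tibble(pt = c("Evt one", "Evt two"),
                            p_base = c(0.2, 0.1)),
    signals = tibble::tibble(ingredient = "a_drug", event_pt = "Evt one",
                             target_rr = 3, tto_scale = 100, tto_shape = 1),
    seed = 7))
  ds <- normalize_drugs(sim$dataset, sim$dictionary)
  sets <- select_reports(ds, "a_drug", "Evt one", roles = c("PS", "concomitant"))
  # brute-force scan, one report at a time
  brute_exposed <- character(0); brute_event <- character(0)
  for (id in ds$cases$report_id) {
    drows <- ds$drugs[ds$drugs$report_id == id, ]
    erows <- ds$events[ds$events$report_id == id, ]
    if (any(drows$ingredient %in% "a_drug" &
              drows$role %in% c("PS", "concomitant"), na.rm = TRUE)) {
      brute_exposed <- c(brute_exposed, id)
    }
    if (any(erows$pt == "Evt one")) brute_event <- c(brute_event, id)
  }
  expect_equal(sets$exposed, sort(brute_exposed))
  expect_equal(sets$with_event, sort(brute_event))
  expect_equal(sets$both, sort(intersect(brute_exposed, brute_event)))
})

test_that("canonical format round-trips all tables", {
  dir <- write_faers_fixture()
  ds <- normalize_drugs(deduplicate(read_srs(dir, "faers")), ltra_dictionary())
  out <- withr::local_tempdir()
  write_srs(ds, out)
  back <- read_srs(out, "synthetic")
  expect_equal(back$cases, ds$cases)
  expect_equal(back$drugs, ds$drugs)
  expect_equal(back$events, ds$events)
})

test_that("JADER and CVAR dialects parse into the canonical form", {
  jd <- read_srs(write_jader_fixture(), "jader")
  expect_equal(jd$dialect, "jader")
  expect_equal(jd$cases$sex, c("female", "male"))
  expect_equal(unique(jd$drugs$role), "suspect")
  cv <- read_srs(write_cvar_fixture(), "cvar")
  expect_equal(cv$drugs$role, c("suspect", "concomitant"))
  expect_equal(cv$events$onset_date[1], as.Date("2019-09-15"))
  # default role policy: suspect
  cvn <- normalize_drugs(cv, ltra_dictionary())
  sets <- select_reports(cvn, "montelukast", "Churg-Strauss syndrome")
  expect_equal(sets$both, "V1")
})
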