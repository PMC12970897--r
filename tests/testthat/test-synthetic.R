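small_cfg <- function(...) {
  generator_config(
    n_reports = 5000,
    drugs = tibble::tibble(ingredient = c("drg", "other"),
                           p_exposure = c(0.05, 0.1)),
    events = tibble::tibble(pt = c("Evt", "Noise"), p_base = c(0.01, 0.05)),
    signals = tibble::tibble(ingredient = "drg", event_pt = "Evt",
                             target_rr = 10, tto_scale = 150, tto_shape = 0.9),
    ...)
}

test_that("the same seed generates byte-identical datasets", {
  s1 <- generate_srs(small_cfg(seed = 91))
  s2 <- generate_srs(small_cfg(seed = 91))
  expect_identical(s1, s2)
  s3 <- generate_srs(small_cfg(seed = 92))
  expect_false(identical(s1$dataset$cases, s3$dataset$cases))
})

test_that("injected duplicates equal the dedup module's removed count", {
  sim <- generate_srs(small_cfg(seed = 93, duplicate_rate = 0.07))
  ds <- deduplicate(sim$dataset)
  expect_equal(dedup_report(ds)$n_case_versions, sim$truth$n_duplicates)
  expect_equal(sim$truth$n_duplicates, round(0.07 * 5000))
  # the kept record is the newer version
  dup_cases <- sim$dataset$cases$case_id[duplicated(sim$dataset$cases$case_id)]
  kept <- ds$cases[ds$cases$case_id %in% dup_cases, ]
  expect_true(all(endsWith(kept$report_id, "-2")))
  # no-duplicate dataset passes through unchanged
  sim0 <- generate_srs(small_cfg(seed = 94, duplicate_rate = 0))
  ds0 <- deduplicate(sim0$dataset)
  expect_equal(dedup_report(ds0)$n_removed, 0)
  expect_equal(ds0$drugs, sim0$dataset$drugs)
})

test_that("empirical marginals converge to the configured probabilities", {
  cfg <- generator_config(
    n_reports = 1e5,
    drugs = tibble::tibble(ingredient = c("d1", "d2"),
                           p_exposure = c(0.02, 0.005)),
    events = tibble::tibble(pt = c("e1", "e2"), p_base = c(0.01, 0.002)),
    signals = tibble::tibble(ingredient = character(), event_pt = character(),
                             target_rr = numeric(), tto_scale = numeric(),
                             tto_shape = numeric()),
    duplicate_rate = 0, seed = 95)
  sim <- generate_srs(cfg)
  for (i in 1:2) {
    p <- cfg$drugs$p_exposure[i]
    se <- sqrt(p * (1 - p) / 1e5)
    expect_lt(abs(sim$truth$exposure_freq$observed[i] - p), 3 * se)
    q <- cfg$events$p_base[i]
    se_q <- sqrt(q * (1 - q) / 1e5)
    expect_lt(abs(sim$truth$event_freq$observed[i] - q), 3 * se_q)
  }
})

test_that("realized 2x2 cells match the closed-form expectations", {
  sim <- generate_srs(generator_config(
    n_reports = 2e5,
    drugs = tibble::tibble(ingredient = "drg", p_exposure = 0.01),
    events = tibble::tibble(pt = "Evt", p_base = 0.001),
    signals = tibble::tibble(ingredient = "drg", event_pt = "Evt",
                             target_rr = 20, tto_scale = 100, tto_shape = 1),
    duplicate_rate = 0, seed = 96))
  p <- sim$truth$pairs
  expect_lt(abs(p$a - p$expected_a) / sqrt(p$expected_a), 4)
  expect_lt(abs(p$c - p$expected_c) / sqrt(p$expected_c), 4)
  # and the contingency module reproduces the presence-level counts
  ds <- normalize_drugs(sim$dataset, sim$dictionary)
  t <- build_table(ds, "drg", "Evt", roles = srs_roles_all())
  expect_equal(t$a, p$a)
  expect_equal(t$b, p$b)
  expect_equal(t$c, p$c)
})

test_that("a null design yields ROR compatible with 1", {
  sim <- generate_srs(generator_config(
    n_reports = 2e5,
    drugs = tibble::tibble(ingredient = "drg", p_exposure = 0.01),
    events = tibble::tibble(pt = "Evt", p_base = 0.005),
    signals = tibble::tibble(ingredient = "drg", event_pt = "Evt",
                             target_rr = 1, tto_scale = 100, tto_shape = 1),
    duplicate_rate = 0, seed = 97))
  ds <- normalize_drugs(sim$dataset, sim$dictionary)
  r <- ror(build_table(ds, "drg", "Evt", roles = srs_roles_all()))
  expect_lt(r$lower, 1)
  expect_gt(r$upper, 1)
})

test_that("a planted RR of 50 is covered by the ROR interval across seeds", {
  hits <- 0
  for (s in 1:20) {
    sim <- generate_srs(generator_config(
      n_reports = 5e5,
      drugs = tibble::tibble(ingredient = "drg", p_exposure = 0.002),
      events = tibble::tibble(pt = "Evt", p_base = 1e-4),
      signals = tibble::tibble(ingredient = "drg", event_pt = "Evt",
                               target_rr = 50, tto_scale = 100, tto_shape = 1),
      duplicate_rate = 0, seed = 1000 + s))
    ds <- normalize_drugs(sim$dataset, sim$dictionary)
    r <- ror(build_table(ds, "drg", "Evt", roles = srs_roles_all()))
    if (r$lower <= 50 && 50 <= r$upper) hits <- hits + 1
  }
  expect_gte(hits, 18)  # >= 90% of 20 replicates
})

test_that("TTO Weibull parameters are recovered at n = 1000", {
  sim <- generate_srs(generator_config(
    n_reports = 25000,
    drugs = tibble::tibble(ingredient = "drg", p_exposure = 0.25),
    events = tibble::tibble(pt = "Evt", p_base = 0.02),
    signals = tibble::tibble(ingredient = "drg", event_pt = "Evt",
                             target_rr = 10, tto_scale = 391.08,
                             tto_shape = 0.76),
    missingness = list(), duplicate_rate = 0, seed = 98))
  ds <- normalize_drugs(sim$dataset, sim$dictionary)
  s <- compute_tto(ds, "drg", "Evt", roles = srs_roles_all())
  expect_gt(length(s$values), 1000)
  f <- fit_weibull(s)
  se_lb <- (log(f$beta_ci[2]) - log(f$beta)) / stats::qnorm(0.975)
  expect_lt(abs(log(f$beta) - log(0.76)) / se_lb, 3)
  se_la <- (log(f$alpha_ci[2]) - log(f$alpha)) / stats::qnorm(0.975)
  expect_lt(abs(log(f$alpha) - log(391.08)) / se_la, 3.5)
})

test_that("an underpowered signal pair warns about expected counts", {
  expect_warning(
    generate_srs(generator_config(
      n_reports = 500,
      drugs = tibble::tibble(ingredient = "drg", p_exposure = 0.01),
      events = tibble::tibble(pt = "Evt", p_base = 1e-4),
      signals = tibble::tibble(ingredient = "drg", event_pt = "Evt",
                               target_rr = 5, tto_scale = 100, tto_shape = 1),
      seed = 99)),
    "< 1")
})

test_that("network fixtures honour the requested overlap", {
  fx <- make_network_fixture(n_drug_targets = 100, n_disease_genes = 150,
                             n_overlap = 81, seed = 100)
  ov <- intersect_targets(fx$drug_targets, fx$disease_genes)
  expect_equal(unname(attr(ov, "venn")["overlap"]), 81)
  expect_equal(length(union_targets(fx$drug_sources)$symbols), 100)
  fx0 <- make_network_fixture(n_drug_targets = 20, n_disease_genes = 30,
                              n_overlap = 0, seed = 101)
  ov0 <- intersect_targets(fx0$drug_targets, fx0$disease_genes)
  expect_length(ov0$symbols, 0)
  expect_error(make_network_fixture(n_drug_targets = 5, n_disease_genes = 5,
                                    n_overlap = 10), "overlap")
})
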