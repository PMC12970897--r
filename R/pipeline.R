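#' Pipeline configuration
#'
#' Single human-readable configuration for an end-to-end run. Accepts a
#' YAML file path or a list with the same structure:
#'
#' ```yaml
#' dialect: synthetic          # faers | jader | cvar | synthetic
#' input_dir: data/            # omit to simulate instead
#' simulate:                   # generator overrides (n_reports, ...)
#'   n_reports: 50000
#' dictionary: ltra            # "ltra" or a CSV path
#' drugs:                      # named drug queries, each a vector
#'   LTRAs: [montelukast, zafirlukast, pranlukast, ibudilast]
#'   montelukast: [montelukast]
#' events: [Eosinophilic granulomatosis with polyangiitis, Churg-Strauss syndrome]
#' subgroups: [age, sex, indication]
#' comedications:
#'   - {drug: montelukast, comed: prednisone, mode: exclude}
#' tto: true
#' netpharm:                   # optional network stage
#'   drug_target_files: [t1.txt, t2.txt]
#'   disease_gene_file: disease.txt
#'   ppi_file: string.tsv
#'   gmt_file: terms.gmt
#' seed: 1
#' ```
#'
#' @param x YAML file path or list.
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  defaults <- list(
    dialect = "synthetic", input_dir = NULL, simulate = list(),
    dictionary = "ltra",
    drugs = list(montelukast = "montelukast"),
    events = egpa_pts(),
    subgroups = character(0), comedications = list(),
    tto = TRUE, netpharm = NULL, seed = 1
  )
  # shallow merge: user values replace defaults wholesale (modifyList would
  # recurse into nested lists and drop unnamed entries)
  for (nm in names(cfg)) defaults[[nm]] <- cfg[[nm]]
  cfg <- defaults
  if (!cfg$dialect %in% c("faers", "jader", "cvar", "synthetic")) {
    abort(sprintf("unknown dialect '%s'", cfg$dialect), class = "srsignal_config_error")
  }
  if (is.null(cfg$input_dir) && is.null(cfg$simulate)) {
    abort("config needs either input_dir or simulate", class = "srsignal_config_error")
  }
  files <- unlist(c(cfg$input_dir,
                    if (!identical(cfg$dictionary, "ltra")) cfg$dictionary,
                    cfg$netpharm[c("drug_target_files", "disease_gene_file",
                                   "ppi_file", "gmt_file")]))
  files <- as.character(files %||% character(0))
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    abort(paste0("referenced path(s) do not exist: ",
                 paste(missing, collapse = ", ")),
          class = "srsignal_config_error")
  }
  if (!is.numeric(cfg$seed)) {
    abort("seed is mandatory and numeric", class = "srsignal_config_error")
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes ingest (or simulate) -> deduplicate -> normalize ->
#' disproportionality for every configured drug query (plus subgroup and
#' co-medication analyses) -> time-to-onset -> network stage, writing
#' CSV tables shaped like published signal tables, descriptive summary
#' counts, and a machine-readable run manifest. Outputs are staged in a
#' temporary directory and moved into place only on success, so a failed
#' stage leaves no partial bundle. With a fixed seed the whole bundle is
#' reproducible byte for byte.
#'
#' @param cfg a [pipeline_config()] (or path/list coercible to one).
#' @param out_dir output directory.
#' @return invisibly, a list with the result tables and the manifest.
#' @export
run_pipeline <- function(cfg, out_dir) {
  cfg <- if (inherits(cfg, "pipeline_config")) cfg else pipeline_config(cfg)
  stage_dir <- tempfile("srsignal_run_")
  dir.create(stage_dir, recursive = TRUE)
  on.exit(unlink(stage_dir, recursive = TRUE), add = TRUE)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)), class = "srsignal_stage_error")
    })
  }
  input_hashes <- character(0)
  sim_dictionary <- NULL

  ds <- run_stage("ingest", {
    if (!is.null(cfg$input_dir)) {
      fs <- list.files(cfg$input_dir, full.names = TRUE)
      input_hashes <- setNames(unname(tools::md5sum(fs)), basename(fs))
      read_srs(cfg$input_dir, cfg$dialect)
    } else {
      sim_args <- modifyList(cfg$simulate %||% list(), list(seed = cfg$seed))
      sim <- generate_srs(do.call(generator_config, sim_args))
      sim_dictionary <- sim$dictionary
      sim$dataset
    }
  })
  ds <- run_stage("deduplicate", deduplicate(ds))
  dict <- run_stage("dictionary", {
    if (identical(cfg$dictionary, "ltra")) {
      sim_dictionary %||% ltra_dictionary()
    } else {
      read_drug_dictionary(cfg$dictionary)
    }
  })
  ds <- run_stage("normalize", normalize_drugs(ds, dict))

  events <- unlist(cfg$events)
  signal_tab <- run_stage("signal", purrr::map_dfr(names(cfg$drugs), function(nm) {
    tryCatch(
      disproportionality(ds, unlist(cfg$drugs[[nm]]), events, label = nm,
                         seed = cfg$seed),
      error = function(e) tibble::tibble(label = nm, evaluable = FALSE,
                                         reason = conditionMessage(e)))
  }))
  readr::write_csv(signal_tab, file.path(stage_dir, "signal_table.csv"), na = "")

  if (length(cfg$subgroups)) {
    sub_tab <- run_stage("subgroup", purrr::map_dfr(names(cfg$drugs), function(nm) {
      purrr::map_dfr(unlist(cfg$subgroups), function(ax) {
        out <- subgroup_analysis(ds, unlist(cfg$drugs[[nm]]), events,
                                 axis = ax, seed = cfg$seed)
        out$label <- nm
        out$axis <- ax
        dplyr::relocate(out, "label", "axis", "level")
      })
    }))
    readr::write_csv(sub_tab, file.path(stage_dir, "subgroup_table.csv"), na = "")
  } else sub_tab <- NULL

  if (length(cfg$comedications)) {
    comed_tab <- run_stage("comedication", purrr::map_dfr(cfg$comedications, function(cm) {
      tryCatch(
        comedication_analysis(ds, cm$drug, events, cm$comed, mode = cm$mode,
                              seed = cfg$seed),
        error = function(e) tibble::tibble(
          label = sprintf("%s [%s %s]", cm$drug, cm$mode, cm$comed),
          evaluable = FALSE, reason = conditionMessage(e)))
    }))
    readr::write_csv(comed_tab, file.path(stage_dir, "comed_table.csv"), na = "")
  } else comed_tab <- NULL

  if (isTRUE(cfg$tto)) {
    tto_tab <- run_stage("tto", purrr::map_dfr(names(cfg$drugs), function(nm) {
      tryCatch({
        s <- compute_tto(ds, unlist(cfg$drugs[[nm]]), events)
        f <- fit_weibull(s)
        tibble::tibble(
          label = nm, n = f$n, median = f$median, q25 = f$q25, q75 = f$q75,
          alpha = f$alpha, alpha_lower = f$alpha_ci[1], alpha_upper = f$alpha_ci[2],
          beta = f$beta, beta_lower = f$beta_ci[1], beta_upper = f$beta_ci[2],
          failure_type = f$failure_type)
      }, error = function(e) tibble::tibble(label = nm, failure_type = NA,
                                            reason = conditionMessage(e)))
    }))
    readr::write_csv(tto_tab, file.path(stage_dir, "tto_table.csv"), na = "")
  } else tto_tab <- NULL

  desc_tab <- run_stage("descriptive", descriptive_summary(ds, cfg$drugs, events))
  readr::write_csv(desc_tab, file.path(stage_dir, "descriptive.csv"), na = "")

  net <- NULL
  if (!is.null(cfg$netpharm)) {
    net <- run_stage("netpharm", {
      np <- cfg$netpharm
      sources <- lapply(unlist(np$drug_target_files), read_gene_list)
      drug_targets <- union_targets(sources)
      disease <- read_gene_list(np$disease_gene_file, name = "disease")
      overlap <- intersect_targets(drug_targets, disease)
      g <- load_ppi(np$ppi_file, threshold = np$threshold %||% 0.4,
                    genes = overlap)
      clusters <- mcode(g)
      gmt <- read_gmt(np$gmt_file)
      enr <- suppressWarnings(enrich(overlap, gmt))
      jsonlite::write_json(as.list(attr(overlap, "venn")),
                           file.path(stage_dir, "venn.json"), auto_unbox = TRUE)
      cl_tab <- purrr::map_dfr(seq_along(clusters), function(i) {
        tibble::tibble(cluster = i, seed = clusters[[i]]$seed,
                       score = clusters[[i]]$score, size = clusters[[i]]$size,
                       members = paste(clusters[[i]]$members, collapse = ";"))
      })
      readr::write_csv(cl_tab, file.path(stage_dir, "clusters.csv"), na = "")
      readr::write_csv(enr, file.path(stage_dir, "enrichment.csv"), na = "")
      list(venn = attr(overlap, "venn"), clusters = clusters, enrichment = enr)
    })
  }

  manifest <- list(
    package = "srsignal",
    version = as.character(utils::packageVersion("srsignal")),
    seed = cfg$seed,
    dialect = cfg$dialect,
    n_reports = n_reports(ds),
    dedup = dedup_report(ds),
    input_hashes = as.list(input_hashes),
    outputs = lapply(
      setNames(nm = list.files(stage_dir)),
      function(f) unname(tools::md5sum(file.path(stage_dir, f))))
  )
  jsonlite::write_json(manifest, file.path(stage_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (f in list.files(stage_dir)) {
    file.copy(file.path(stage_dir, f), file.path(out_dir, f), overwrite = TRUE)
  }
  invisible(list(signal = signal_tab, subgroup = sub_tab, comed = comed_tab,
                 tto = tto_tab, descriptive = desc_tab, netpharm = net,
                 manifest = manifest))
}

#' Descriptive summary of drug-event cases
#'
#' Counts of reporting year, sex, age band, weight band, reporter and
#' outcome among the reports carrying each configured drug query and the
#' target event.
#'
#' @param ds an [srs_dataset()].
#' @param drug_queries named list of ingredient vectors.
#' @param event_pts target event terms.
#' @return long tibble with `label`, `variable`, `level`, `n`.
#' @export
descriptive_summary <- function(ds, drug_queries, event_pts) {
  proto <- tibble::tibble(label = character(), variable = character(),
                          level = character(), n = integer())
  dplyr::bind_rows(proto, purrr::map_dfr(names(drug_queries), function(nm) {
    sets <- select_reports(ds, unlist(drug_queries[[nm]]), event_pts)
    cc <- ds$cases[ds$cases$report_id %in% sets$both, ]
    if (!nrow(cc)) return(NULL)
    count_var <- function(var, values) {
      tab <- table(values, useNA = "no")
      if (!length(tab)) return(NULL)
      tibble::tibble(label = nm, variable = var,
                     level = names(tab), n = as.integer(tab))
    }
    dplyr::bind_rows(
      count_var("year", cc$event_year),
      count_var("sex", cc$sex),
      count_var("age_band", dplyr::case_when(
        is.na(cc$age) ~ NA_character_,
        cc$age < 18 ~ "<18", cc$age < 65 ~ "18-65", TRUE ~ ">=65")),
      count_var("weight_band", dplyr::case_when(
        is.na(cc$weight) ~ NA_character_,
        cc$weight < 50 ~ "<50kg", TRUE ~ ">=50kg")),
      count_var("reporter", cc$reporter),
      count_var("outcome", unlist(strsplit(cc$outcomes[!is.na(cc$outcomes)], ";",
                                           fixed = TRUE)))
    )
  }))
}
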