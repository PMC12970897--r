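#' Drug-name dictionary
#'
#' Maps verbatim drug names (generic, trade and former names) to canonical
#' ingredients. Lookup is case-insensitive, whitespace-normalized and
#' Unicode-folded via [norm_label()]. Every ingredient maps to itself.
#'
#' @param df data frame with columns `name` and `ingredient`.
#' @return a `drug_dictionary` object.
#' @export
drug_dictionary <- function(df) {
  df <- tibble::as_tibble(df)
  if (!all(c("name", "ingredient") %in% names(df))) {
    abort("drug dictionary needs columns 'name' and 'ingredient'")
  }
  df$ingredient <- norm_label(df$ingredient)
  df$key <- norm_label(df$name)
  # ensure self-mapping for every ingredient
  self <- tibble::tibble(name = unique(df$ingredient),
                         ingredient = unique(df$ingredient),
                         key = unique(df$ingredient))
  df <- dplyr::distinct(dplyr::bind_rows(df[c("name", "ingredient", "key")], self),
                        .data$key, .keep_all = TRUE)
  structure(list(table = df), class = "drug_dictionary")
}

#' @rdname drug_dictionary
#' @param path two-column CSV file (`name,ingredient`).
#' @export
read_drug_dictionary <- function(path) {
  drug_dictionary(readr::read_csv(path, col_types = "cc", progress = FALSE))
}

#' @export
print.drug_dictionary <- function(x, ...) {
  cat(sprintf("<drug_dictionary> %d names -> %d ingredients\n",
              nrow(x$table), dplyr::n_distinct(x$table$ingredient)))
  invisible(x)
}

#' Look up canonical ingredients for verbatim names
#' @param dict a [drug_dictionary()].
#' @param names character vector of verbatim drug names.
#' @return character vector of ingredients (`NA` where unmatched).
#' @export
dict_lookup <- function(dict, names) {
  stopifnot(inherits(dict, "drug_dictionary"))
  idx <- match(norm_label(names), dict$table$key)
  dict$table$ingredient[idx]
}

#' Bundled leukotriene receptor antagonist dictionary
#'
#' Generic, trade and former names for montelukast, zafirlukast,
#' pranlukast and ibudilast, shipped as `extdata/ltra_dictionary.csv`.
#' @return a `drug_dictionary`.
#' @export
ltra_dictionary <- function() {
  read_drug_dictionary(system.file("extdata", "ltra_dictionary.csv",
                                   package = "srsignal", mustWork = TRUE))
}

#' Default EGPA event query
#'
#' MedDRA preferred terms used to retrieve eosinophilic granulomatosis
#' with polyangiitis cases; includes the legacy "Churg-Strauss syndrome"
#' term under which pre-2004 reports are coded.
#' @return character vector of preferred terms.
#' @export
egpa_pts <- function() {
  c("Eosinophilic granulomatosis with polyangiitis", "Churg-Strauss syndrome")
}
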