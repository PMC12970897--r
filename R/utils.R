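#' Normalize a label for matching
#'
#' Unicode NFKC normalization, case folding and whitespace squashing.
#' Used for every drug-name and event-term comparison so that trade names
#' and preferred terms match across databases regardless of case,
#' full-width characters or stray spaces.
#'
#' @param x character vector.
#' @return normalized character vector of the same length.
#' @export
norm_label <- function(x) {
  x <- stringi::stri_trans_nfkc(as.character(x))
  x <- stringr::str_squish(x)
  stringr::str_to_lower(x)
}

# run expr under a fixed RNG seed, restoring global RNG state afterwards
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# log(exp(x) + exp(y)) element-wise without overflow
log_sum_exp2 <- function(x, y) {
  m <- pmax(x, y)
  r <- m + log(exp(x - m) + exp(y - m))
  # both -Inf
  r[is.nan(r)] <- -Inf
  r
}

#' Parse dates that may be partial
#'
#' Accepts ISO (`2020-01-31`), compact (`20200131`) and partial forms
#' (`2020`, `202001`, `2020-01`). Missing month/day components are imputed
#' to 1 and flagged; unparseable strings become `NA` and are counted.
#'
#' @param x character vector of date strings.
#' @return a `Date` vector with attributes `imputed` (logical, partial
#'   dates) and `n_failed` (count of non-missing strings that failed to
#'   parse).
#' @export
parse_srs_date <- function(x) {
  x <- stringr::str_trim(as.character(x))
  x[x %in% c("", "NA", "N/A")] <- NA_character_
  digits <- stringr::str_remove_all(x, "-")
  out <- rep(as.Date(NA), length(x))
  imputed <- rep(FALSE, length(x))
  ok8 <- !is.na(digits) & stringr::str_detect(digits, "^\\d{8}$")
  out[ok8] <- as.Date(digits[ok8], format = "%Y%m%d")
  ok6 <- !is.na(digits) & stringr::str_detect(digits, "^\\d{6}$")
  out[ok6] <- as.Date(paste0(digits[ok6], "01"), format = "%Y%m%d")
  imputed[ok6] <- TRUE
  ok4 <- !is.na(digits) & stringr::str_detect(digits, "^\\d{4}$")
  out[ok4] <- as.Date(paste0(digits[ok4], "0101"), format = "%Y%m%d")
  imputed[ok4] <- TRUE
  failed <- !is.na(x) & is.na(out)
  imputed[is.na(out)] <- NA
  structure(out, imputed = imputed, n_failed = sum(failed))
}

# left-pad to a fixed width so lexicographic order equals numeric order
pad_key <- function(x, width = 24) {
  formatC(as.character(x), width = width, flag = "0")
}
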