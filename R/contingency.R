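#' 2x2 contingency table for a drug-event pair
#'
#' Cell convention for report-level disproportionality: `a` reports with
#' the target drug and target event, `b` target drug with other events,
#' `c` other drugs with the target event, `d` neither.
#'
#' @param a,b,c,d non-negative integer cell counts, `a+b+c+d > 0`.
#' @return a `contingency_table` object.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = as.double(a), b = as.double(b), c = as.double(c),
             d = as.double(d))
  if (any(is.na(cells)) || any(cells < 0)) {
    abort("all cells must be non-negative numbers")
  }
  if (sum(cells) <= 0) abort("table total must be positive")
  structure(as.list(cells), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<2x2 table> a=%g b=%g c=%g d=%g (N=%g)\n",
              x$a, x$b, x$c, x$d, x$a + x$b + x$c + x$d))
  invisible(x)
}

table_n <- function(t) t$a + t$b + t$c + t$d

#' Build the 2x2 table for a drug(-set) x event pair
#'
#' Cells are computed at report level from [select_reports()]: `a+b` is
#' the number of exposed reports, `a+c` the number of event reports, and
#' `N` the total number of reports in the dataset.
#'
#' @inheritParams select_reports
#' @return a [contingency_table()].
#' @export
build_table <- function(ds, ingredients, event_pts, roles = NULL) {
  sets <- select_reports(ds, ingredients, event_pts, roles)
  N <- n_reports(ds)
  a <- length(sets$both)
  b <- length(sets$exposed) - a
  c <- length(sets$with_event) - a
  d <- N - a - b - c
  if (a + b == 0) abort("degenerate table: no exposed reports")
  if (a + c == 0) abort("degenerate table: no reports with the event")
  contingency_table(a, b, c, d)
}

haldane <- function(t) contingency_table(t$a + 0.5, t$b + 0.5, t$c + 0.5, t$d + 0.5)

#' Reporting odds ratio
#'
#' `ROR = ad / bc` with the Wald 95% interval
#' `exp(ln ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param t a [contingency_table()].
#' @param haldane_correction with a zero cell, add 0.5 to every cell
#'   (flagged in the output) instead of erroring. Default off.
#' @param conf_level confidence level (default 0.95).
#' @return list with `estimate`, `lower`, `upper`, `corrected`.
#' @export
ror <- function(t, haldane_correction = FALSE, conf_level = 0.95) {
  corrected <- FALSE
  if (min(t$a, t$b, t$c, t$d) == 0) {
    if (!haldane_correction) {
      abort("zero cell makes the ROR undefined; set haldane_correction = TRUE to add 0.5 to all cells")
    }
    t <- haldane(t)
    corrected <- TRUE
  }
  est <- (t$a * t$d) / (t$b * t$c)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d)
  list(estimate = est, lower = exp(log(est) - z * se),
       upper = exp(log(est) + z * se), corrected = corrected)
}

#' Proportional reporting ratio and Pearson chi-square
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]` with the Wald interval
#' `exp(ln PRR +/- z * sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`, and the
#' Pearson statistic `N(ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)]` without
#' continuity correction.
#'
#' @inheritParams ror
#' @return list with `estimate`, `lower`, `upper`, `chi2`, `corrected`.
#' @export
prr_chi2 <- function(t, haldane_correction = FALSE, conf_level = 0.95) {
  corrected <- FALSE
  if (t$a + t$b == 0 || t$c + t$d == 0) abort("PRR needs exposed and non-exposed reports")
  if (t$a == 0 || t$c == 0) {
    if (!haldane_correction) {
      abort("zero a or c cell makes the PRR undefined; set haldane_correction = TRUE")
    }
    t <- haldane(t)
    corrected <- TRUE
  }
  est <- (t$a / (t$a + t$b)) / (t$c / (t$c + t$d))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(1 / t$a - 1 / (t$a + t$b) + 1 / t$c - 1 / (t$c + t$d))
  N <- table_n(t)
  chi2 <- N * (t$a * t$d - t$b * t$c)^2 /
    ((t$a + t$b) * (t$c + t$d) * (t$a + t$c) * (t$b + t$d))
  list(estimate = est, lower = exp(log(est) - z * se),
       upper = exp(log(est) + z * se), chi2 = chi2, corrected = corrected)
}

#' Expected count under independence and relative reporting ratio
#'
#' `E = (a+b)(a+c)/N` and `RR = a/E`, the observed-to-expected reporting
#' ratio that the information component and EBGM shrink towards.
#'
#' @param t a [contingency_table()].
#' @return list with `E` and `rr`.
#' @export
expected_count <- function(t) {
  N <- table_n(t)
  E <- (t$a + t$b) * (t$a + t$c) / N
  list(E = E, rr = t$a / E)
}

#' Reconstruct a 2x2 table from published marginals and an ROR anchor
#'
#' Published disproportionality tables usually print `a`, the exposure
#' and event margins and the ROR point estimate, but not the background
#' cell `d`. Since `ROR = ad/(bc)`, `d` follows by inversion, after which
#' every other statistic of the row can be recomputed.
#'
#' @param a reports with drug and event.
#' @param n_exposed exposed reports (`a+b`).
#' @param n_event event reports (`a+c`).
#' @param ror_anchor printed ROR point estimate.
#' @return a [contingency_table()] (with a fractional `d` cell reflecting
#'   rounding of the anchor).
#' @export
reconstruct_table <- function(a, n_exposed, n_event, ror_anchor) {
  stopifnot(n_exposed > a, n_event > a, ror_anchor > 0)
  b <- n_exposed - a
  c <- n_event - a
  d <- ror_anchor * b * c / a
  contingency_table(a, b, c, d)
}
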