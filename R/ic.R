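#' Bayesian information component
#'
#' The BCPNN information component for a drug-event pair with observed
#' count `a` and expected count `E`:
#'
#' * variant `"raw"` — `IC = log2(a/E)`, the convention of published
#'   signal tables (which satisfy `IC = log2(EBGM)` row by row);
#' * variant `"shrunk"` — `IC = log2((a + 0.5) / (E + 0.5))`, the
#'   credibility-shrunk form.
#'
#' The 2.5th credibility percentile is reported two ways: `ic025`, the
#' closed approximation `IC - 3.3 (a + 0.5)^(-1/2) - 2 (a + 0.5)^(-3/2)`,
#' and `ic025_mc`, the Monte-Carlo 2.5th percentile of `log2(lambda)`
#' under the `Gamma(a + 0.5, E + 0.5)` posterior.
#'
#' @param a observed report count.
#' @param E expected count under independence (`> 0`).
#' @param variant `"raw"` (default) or `"shrunk"`.
#' @param n_mc Monte-Carlo sample size for `ic025_mc`.
#' @param seed optional seed for the Monte-Carlo draw (global RNG state
#'   is restored).
#' @return list with `ic`, `ic025`, `ic025_mc`, `variant`.
#' @export
information_component <- function(a, E, variant = c("raw", "shrunk"),
                                  n_mc = 1e5, seed = NULL) {
  variant <- match.arg(variant)
  if (E <= 0) abort("E must be positive")
  if (variant == "raw" && a == 0) {
    abort("raw IC is undefined at a = 0; use the shrunk variant")
  }
  ic <- switch(variant,
    raw = log2(a / E),
    shrunk = log2((a + 0.5) / (E + 0.5)))
  approx <- ic - 3.3 * (a + 0.5)^(-0.5) - 2 * (a + 0.5)^(-1.5)
  draw <- function() quantile(log2(rgamma(n_mc, shape = a + 0.5, rate = E + 0.5)),
                              0.025, names = FALSE)
  mc <- if (is.null(seed)) draw() else with_seed(seed, draw())
  list(ic = ic, ic025 = approx, ic025_mc = mc, variant = variant)
}
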