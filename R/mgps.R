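#' Two-component gamma-Poisson prior (MGPS)
#'
#' Hyperparameters of DuMouchel's multi-item gamma-Poisson shrinker: the
#' relative reporting rate `lambda` of a drug-event pair is given the
#' mixture prior `w * Gamma(alpha1, beta1) + (1-w) * Gamma(alpha2, beta2)`
#' (shape/rate), and the observed count is `a ~ Poisson(lambda * E)`.
#'
#' @param alpha1,beta1,alpha2,beta2 positive gamma shape/rate parameters.
#' @param w mixture weight of the first component, in `[0, 1]`.
#' @return a `gamma_poisson_prior` object.
#' @export
gamma_poisson_prior <- function(alpha1 = 0.2, beta1 = 0.1,
                                alpha2 = 2, beta2 = 4, w = 1 / 3) {
  if (any(c(alpha1, beta1, alpha2, beta2) <= 0)) {
    abort("gamma hyperparameters must be positive")
  }
  if (w < 0 || w > 1) abort("mixture weight must lie in [0, 1]")
  structure(list(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2,
                 beta2 = beta2, w = w),
            class = "gamma_poisson_prior")
}

#' @export
print.gamma_poisson_prior <- function(x, ...) {
  cat(sprintf(
    "<gamma_poisson_prior> w=%.3f Gamma(%.4g, %.4g) + %.3f Gamma(%.4g, %.4g)\n",
    x$w, x$alpha1, x$beta1, 1 - x$w, x$alpha2, x$beta2))
  if (!is.null(attr(x, "fit"))) {
    f <- attr(x, "fit")
    cat(sprintf("  fitted: loglik=%.2f converged=%s\n", f$loglik, f$converged))
  }
  invisible(x)
}

# log marginal likelihood of one observation under one gamma component:
# a | lambda ~ Poisson(lambda E), lambda ~ Gamma(alpha, beta)
# => a ~ NegBinom(size = alpha, prob = beta / (beta + E))
log_marginal <- function(a, E, alpha, beta) {
  dnbinom(a, size = alpha, prob = beta / (beta + E), log = TRUE)
}

mixture_loglik <- function(a, E, p) {
  l1 <- log(p$w) + log_marginal(a, E, p$alpha1, p$beta1)
  l2 <- log1p(-p$w) + log_marginal(a, E, p$alpha2, p$beta2)
  sum(log_sum_exp2(l1, l2))
}

#' Fit the gamma-Poisson mixture prior by marginal maximum likelihood
#'
#' Maximizes the marginal likelihood of the two-component
#' negative-binomial mixture over `(alpha1, beta1, alpha2, beta2, w)` on
#' an unconstrained transformed scale (log for the gamma parameters,
#' logit for the weight), starting from DuMouchel's conventional values
#' `(0.2, 0.1, 2, 4, 1/3)`.
#'
#' @param a integer vector of observed counts, one per drug-event pair.
#' @param E positive vector of expected counts under independence.
#' @param init starting [gamma_poisson_prior()].
#' @param maxit maximum optimizer iterations.
#' @return the fitted `gamma_poisson_prior`, carrying a `fit` attribute
#'   with `loglik`, `converged` and the optimizer details. Non-convergence
#'   raises an error whose condition carries the best-so-far prior in
#'   `$prior`.
#' @export
fit_gamma_poisson_prior <- function(a, E, init = gamma_poisson_prior(),
                                    maxit = 500) {
  if (length(a) != length(E)) abort("a and E must have equal length")
  if (length(a) < 2) abort("need at least 2 drug-event pairs")
  if (any(E <= 0)) abort("all expected counts must be positive")
  # clamp the working scale so optimizer excursions cannot overflow
  unpack <- function(th) {
    th <- pmin(pmax(th, -25), 25)
    gamma_poisson_prior(
      alpha1 = exp(th[1]), beta1 = exp(th[2]),
      alpha2 = exp(th[3]), beta2 = exp(th[4]), w = plogis(th[5]))
  }
  th0 <- c(log(init$alpha1), log(init$beta1), log(init$alpha2),
           log(init$beta2), qlogis(init$w))
  nll <- function(th) -mixture_loglik(a, E, unpack(th))
  opt <- optim(th0, nll, method = "BFGS", control = list(maxit = maxit))
  prior <- unpack(opt$par)
  attr(prior, "fit") <- list(loglik = -opt$value,
                             converged = opt$convergence == 0,
                             counts = opt$counts, n_pairs = length(a))
  if (opt$convergence != 0) {
    abort(sprintf("prior fit did not converge (optim code %d)", opt$convergence),
          class = "srsignal_fit_error", prior = prior)
  }
  prior
}

#' Empirical Bayes geometric mean and its lower bound
#'
#' With a [gamma_poisson_prior()], the posterior of the relative
#' reporting rate given `(a, E)` is a two-component gamma mixture with
#' updated parameters `(alpha_i + a, beta_i + E)` and weights
#' proportional to each component's marginal likelihood. `EBGM =
#' exp(E[ln lambda])` and `EB05` is the posterior 5th percentile, solved
#' numerically.
#'
#' Without a prior (`prior = NULL`, the default reporting variant), the
#' large-count unshrunk limit is returned: `EBGM = a/E` and `EBGM05` the
#' 2.5th percentile of the limiting `Gamma(a, E)` posterior, matching the
#' "lower limit of the 95% CI" convention of published signal tables.
#'
#' @param a observed report count.
#' @param E expected count under independence (`> 0`).
#' @param prior a `gamma_poisson_prior`, or `NULL` for the unshrunk
#'   variant.
#' @param p lower-tail probability for the bound (default 0.05 with a
#'   prior, 0.025 unshrunk).
#' @return list with `ebgm`, `ebgm05`, `shrunk`.
#' @export
ebgm_score <- function(a, E, prior = NULL, p = NULL) {
  if (E <= 0) abort("E must be positive")
  if (is.null(prior)) {
    p <- p %||% 0.025
    est <- a / E
    lo <- if (a > 0) qgamma(p, shape = a, rate = E) else 0
    return(list(ebgm = est, ebgm05 = lo, shrunk = FALSE))
  }
  p <- p %||% 0.05
  l1 <- log(prior$w) + log_marginal(a, E, prior$alpha1, prior$beta1)
  l2 <- log1p(-prior$w) + log_marginal(a, E, prior$alpha2, prior$beta2)
  q1 <- exp(l1 - log_sum_exp2(l1, l2))
  q2 <- 1 - q1
  s1 <- prior$alpha1 + a; r1 <- prior$beta1 + E
  s2 <- prior$alpha2 + a; r2 <- prior$beta2 + E
  mean_log <- q1 * (digamma(s1) - log(r1)) + q2 * (digamma(s2) - log(r2))
  est <- exp(mean_log)
  cdf <- function(x) q1 * pgamma(x, s1, rate = r1) + q2 * pgamma(x, s2, rate = r2) - p
  hi <- max(qgamma(p, s1, rate = r1), qgamma(p, s2, rate = r2), est) + 1
  lo_bound <- uniroot(cdf, lower = 0, upper = hi, extendInt = "upX",
                      tol = 1e-10)$root
  list(ebgm = est, ebgm05 = lo_bound, shrunk = TRUE)
}
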