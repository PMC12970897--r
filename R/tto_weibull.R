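#' Time-to-onset sample for a drug-event pair
#'
#' For every report carrying the index drug (under the dialect's role
#' policy) and the target event, the time-to-onset is the event onset
#' date minus the earliest start date of the index drug, in days.
#' Reports with a missing start or onset date, or a non-positive
#' interval, are excluded with reason counts. Records whose dates were
#' imputed from partial dates can be excluded via `include_imputed`.
#'
#' @inheritParams select_reports
#' @param include_imputed keep records with day/month-imputed dates
#'   (default `TRUE`).
#' @return a `tto_sample`: list with `values` (positive days),
#'   `report_ids`, and `excluded` counts
#'   (`missing_date`, `non_positive`, `imputed`).
#' @export
compute_tto <- function(ds, ingredients, event_pts, roles = NULL,
                        include_imputed = TRUE) {
  sets <- select_reports(ds, ingredients, event_pts, roles)
  ids <- sets$both
  ing <- norm_label(ingredients)
  pts <- norm_label(event_pts)
  starts <- ds$drugs |>
    dplyr::filter(.data$report_id %in% ids, !is.na(.data$ingredient),
                  norm_label(.data$ingredient) %in% ing) |>
    dplyr::group_by(.data$report_id) |>
    dplyr::summarise(
      start = if (all(is.na(.data$start_date))) as.Date(NA) else
        min(.data$start_date, na.rm = TRUE),
      start_imp = any(.data$start_imputed[!is.na(.data$start_date)] %in% TRUE))
  onsets <- ds$events |>
    dplyr::filter(.data$report_id %in% ids, norm_label(.data$pt) %in% pts) |>
    dplyr::group_by(.data$report_id) |>
    dplyr::summarise(
      onset = if (all(is.na(.data$onset_date))) as.Date(NA) else
        min(.data$onset_date, na.rm = TRUE),
      onset_imp = any(.data$onset_imputed[!is.na(.data$onset_date)] %in% TRUE))
  joined <- dplyr::inner_join(starts, onsets, by = "report_id")
  missing <- is.na(joined$start) | is.na(joined$onset)
  tto <- as.numeric(joined$onset - joined$start)
  nonpos <- !missing & tto <= 0
  imputed <- !missing & !nonpos & (joined$start_imp | joined$onset_imp)
  keep <- !missing & !nonpos & (include_imputed | !imputed)
  n_imp_excluded <- if (include_imputed) 0L else sum(imputed)
  if (!any(keep)) abort("no computable time-to-onset values for this pair")
  structure(list(
    values = tto[keep],
    report_ids = joined$report_id[keep],
    excluded = c(missing_date = sum(missing), non_positive = sum(nonpos),
                 imputed = n_imp_excluded)
  ), class = "tto_sample")
}

#' @export
print.tto_sample <- function(x, ...) {
  cat(sprintf("<tto_sample> n=%d, median=%.0f days (excluded: %s)\n",
              length(x$values), median(x$values),
              paste(names(x$excluded), x$excluded, sep = "=", collapse = ", ")))
  invisible(x)
}

weibull_loglik <- function(la, lb, x) {
  alpha <- exp(la); beta <- exp(lb)
  n <- length(x)
  n * log(beta) - n * beta * log(alpha) + (beta - 1) * sum(log(x)) -
    sum((x / alpha)^beta)
}

# numeric Hessian of the loglik in (log alpha, log beta)
weibull_obs_info <- function(la, lb, x, h = 1e-4) {
  f <- function(p) weibull_loglik(p[1], p[2], x)
  H <- matrix(0, 2, 2)
  p0 <- c(la, lb)
  for (i in 1:2) for (j in 1:2) {
    ei <- ej <- c(0, 0); ei[i] <- h; ej[j] <- h
    H[i, j] <- (f(p0 + ei + ej) - f(p0 + ei - ej) -
                  f(p0 - ei + ej) + f(p0 - ei - ej)) / (4 * h^2)
  }
  -H
}

#' Weibull maximum-likelihood fit for time-to-onset data
#'
#' Fits the two-parameter Weibull distribution (scale `alpha` in days,
#' shape `beta`) by maximum likelihood: the profile score equation for
#' `beta`, `1/beta = sum(t^beta log t)/sum(t^beta) - mean(log t)`, is
#' solved numerically and `alpha` follows in closed form as
#' `(mean(t^beta))^(1/beta)`. 95% confidence intervals come from the
#' observed information on `(log alpha, log beta)`, back-transformed.
#' A `beta` below 1 with its whole interval below 1 marks a hazard that
#' decreases with treatment time (early failure); see
#' [classify_failure_type()].
#'
#' @param s a `tto_sample` from [compute_tto()], or a numeric vector of
#'   positive durations in days.
#' @param conf_level confidence level (default 0.95).
#' @return a `weibull_fit`: list with `alpha`, `beta`, `alpha_ci`,
#'   `beta_ci`, `loglik`, `n`, `median`, `q25`, `q75`, `failure_type`.
#' @export
fit_weibull <- function(s, conf_level = 0.95) {
  x <- if (inherits(s, "tto_sample")) s$values else as.numeric(s)
  if (length(x) < 3) abort("need at least 3 time-to-onset values")
  if (any(x <= 0)) abort("all durations must be positive")
  if (diff(range(x)) == 0) abort("degenerate likelihood: all values identical")
  lx <- log(x)
  score <- function(beta) {
    xb <- x^beta
    sum(xb * lx) / sum(xb) - mean(lx) - 1 / beta
  }
  # bracket the root of the profile score
  lo <- 1e-3; hi <- 1
  while (score(hi) < 0 && hi < 1e3) hi <- hi * 2
  beta <- uniroot(score, c(lo, hi), tol = 1e-10)$root
  alpha <- mean(x^beta)^(1 / beta)
  la <- log(alpha); lb <- log(beta)
  info <- weibull_obs_info(la, lb, x)
  V <- solve(info)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se_la <- sqrt(V[1, 1]); se_lb <- sqrt(V[2, 2])
  fit <- structure(list(
    alpha = alpha, beta = beta,
    alpha_ci = c(exp(la - z * se_la), exp(la + z * se_la)),
    beta_ci = c(exp(lb - z * se_lb), exp(lb + z * se_lb)),
    loglik = weibull_loglik(la, lb, x),
    n = length(x),
    median = median(x),
    q25 = quantile(x, 0.25, names = FALSE),
    q75 = quantile(x, 0.75, names = FALSE)
  ), class = "weibull_fit")
  fit$failure_type <- classify_failure_type(fit)
  fit
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf(
    "<weibull_fit> n=%d median=%.0f (%.0f-%.0f) alpha=%.2f (%.2f-%.2f) beta=%.2f (%.2f-%.2f) %s\n",
    x$n, x$median, x$q25, x$q75, x$alpha, x$alpha_ci[1], x$alpha_ci[2],
    x$beta, x$beta_ci[1], x$beta_ci[2], x$failure_type))
  invisible(x)
}

#' Hazard failure-type classification from the Weibull shape
#'
#' `early` when the shape estimate and its whole confidence interval lie
#' below 1 (hazard decreases over time), `wear-out` when both lie above 1
#' (hazard increases), `random` otherwise (interval contains or touches
#' 1, constant hazard).
#'
#' @param f a `weibull_fit`, or a shape estimate (with `ci`).
#' @param ci length-2 confidence interval when `f` is a bare estimate.
#' @return `"early"`, `"random"` or `"wear-out"`.
#' @export
classify_failure_type <- function(f, ci = NULL) {
  if (inherits(f, "weibull_fit")) {
    beta <- f$beta; ci <- f$beta_ci
  } else {
    beta <- f
    if (is.null(ci)) abort("supply the shape confidence interval")
  }
  if (beta < 1 && ci[2] < 1) "early"
  else if (beta > 1 && ci[1] > 1) "wear-out"
  else "random"
}

#' Histogram bins for time-to-onset values
#'
#' Fixed-width binning of a TTO sample; total count is conserved.
#'
#' @param s a `tto_sample` or numeric vector of days.
#' @param binwidth bin width in days (default 30).
#' @return tibble with `bin_start`, `bin_end`, `count`.
#' @export
tto_histogram <- function(s, binwidth = 30) {
  x <- if (inherits(s, "tto_sample")) s$values else as.numeric(s)
  bin <- floor((x - 1e-9) / binwidth)
  tab <- table(bin)
  tibble::tibble(
    bin_start = as.numeric(names(tab)) * binwidth,
    bin_end = (as.numeric(names(tab)) + 1) * binwidth,
    count = as.integer(tab)
  )
}
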