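#' Posterior draws of projected coverage
#'
#' Per posterior draw, projected coverage at year `t*` is
#' `inv_logit(alpha + beta * (t* - t0))` (plus the group offsets, and the
#' group slope offsets under the interaction model). This is the posterior
#' of the systematic trend, without adding residual noise; set
#' `predictive = TRUE` to add a new-observation Gaussian residual on the
#' logit scale before back-transforming.
#'
#' @param fit An `uhc_draws` object.
#' @param years Calendar years to project to.
#' @param group Group label (required if the fit is grouped; the reference
#'   group is the first label alphabetically).
#' @param predictive Add residual noise (default `FALSE`).
#' @return Matrix of draws (rows) by years (columns), on the proportion
#'   scale in (0,1).
#' @export
projection_draws <- function(fit, years, group = NULL, predictive = FALSE) {
  stopifnot(inherits(fit, "uhc_draws"))
  d <- fit$draws
  t <- years - fit$t0
  eta <- outer(d$alpha, rep(1, length(t))) + outer(d$beta, t)
  if (!is.null(fit$groups)) {
    if (is.null(group)) stop("grouped fit: a group label is required", call. = FALSE)
    if (!group %in% fit$groups) stop("unknown group: ", group, call. = FALSE)
    if (group != fit$groups[1L]) {
      eta <- eta + d[[paste0("g_", group)]]
      gb <- paste0("gb_", group)
      if (gb %in% names(d)) eta <- eta + outer(d[[gb]], t)
    }
  }
  if (predictive) {
    eta <- eta + matrix(stats::rnorm(length(eta), 0, sqrt(d$sigma2)),
                        nrow = nrow(eta))
  }
  m <- inv_logit(eta)
  colnames(m) <- years
  m
}

#' Projected coverage with credible intervals
#'
#' Summaries (posterior mean and central 95% credible interval) of projected
#' coverage on the percent scale, per requested year (and group).
#'
#' @inheritParams projection_draws
#' @return Tibble: `year`, (`group`,) `mean`, `ci_lo`, `ci_hi`, in percent.
#' @export
project <- function(fit, years, group = NULL, predictive = FALSE) {
  groups <- if (is.null(fit$groups) || !is.null(group)) list(group)
            else as.list(fit$groups)
  out <- lapply(groups, function(g) {
    m <- 100 * projection_draws(fit, years, group = g, predictive = predictive)
    q <- apply(m, 2L, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
    r <- tibble::tibble(year = years, mean = unname(colMeans(m)),
                        ci_lo = unname(q[1L, ]), ci_hi = unname(q[2L, ]))
    if (!is.null(g)) r <- dplyr::bind_cols(tibble::tibble(group = g), r)
    r
  })
  dplyr::bind_rows(out)
}

#' Probability of meeting the coverage target
#'
#' Fraction of posterior draws whose projected coverage at `year` is at
#' least `target` (default: 80% essential-service coverage by 2030).
#'
#' @inheritParams projection_draws
#' @param year Target year (default 2030).
#' @param target Coverage target as a proportion (default 0.80).
#' @return Probability in `[0, 1]`.
#' @export
prob_target_coverage <- function(fit, year = 2030, target = 0.80, group = NULL) {
  mean(projection_draws(fit, year, group = group)[, 1L] >= target)
}

#' Probability of (near-)complete financial risk protection
#'
#' A 100% financial-risk-protection target means 0% incidence of hardship,
#' which has probability zero under any continuous posterior; the target is
#' therefore operationalized as incidence below a small `epsilon` (default 1
#' percentage point) at the target year.
#'
#' @param fit An `uhc_draws` fitted to a hardship-incidence trend.
#' @param year Target year (default 2030).
#' @param epsilon Incidence threshold as a proportion (default 0.01).
#' @param group Optional group label for grouped fits.
#' @return Probability in `[0, 1]`.
#' @export
prob_financial_protection <- function(fit, year = 2030, epsilon = 0.01,
                                      group = NULL) {
  mean(projection_draws(fit, year, group = group)[, 1L] < epsilon)
}

#' Annual rate of change of projected coverage
#'
#' Endpoint geometric rate per draw:
#' `100 * ((coverage(end) / coverage(start))^(1/(end-start)) - 1)`,
#' summarized by the posterior mean and central 95% credible interval.
#'
#' @inheritParams projection_draws
#' @param start_year,end_year Period over which the rate is computed.
#' @return Tibble: `rate_mean`, `rate_lo`, `rate_hi` (percent per year).
#' @export
annual_rate_of_change <- function(fit, start_year, end_year, group = NULL) {
  stopifnot(start_year < end_year)
  m <- projection_draws(fit, c(start_year, end_year), group = group)
  rate <- 100 * ((m[, 2L] / m[, 1L])^(1 / (end_year - start_year)) - 1)
  q <- stats::quantile(rate, c(0.025, 0.975), names = FALSE)
  tibble::tibble(rate_mean = mean(rate), rate_lo = q[1L], rate_hi = q[2L])
}
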