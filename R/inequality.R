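#' Slope and relative indices of inequality
#'
#' Weighted least-squares regression of the quintile-level outcome (percent)
#' on the quintiles' relative-rank midpoints, weighted by the quintile
#' population shares. The slope index of inequality (SII) is the fitted
#' difference between the extremes of the wealth distribution, fitted(1) -
#' fitted(0), in percentage points; the relative index of inequality (RII)
#' is the ratio fitted(1)/fitted(0) (richest over poorest), so an outcome
#' concentrated among the rich gives SII > 0 and RII > 1 while a burden
#' concentrated among the poor (e.g. catastrophic spending) gives SII < 0
#' and RII < 1.
#'
#' @param values Outcome per quintile (Q1 poorest .. Q5 richest), percent.
#' @param ranks Relative-rank midpoints in (0,1), see
#'   [quintile_relative_ranks()]. Default: equal quintiles.
#' @param shares Quintile population shares (weights), summing to 1.
#' @return List with `sii`, `rii`, `fitted0`, `fitted1`. `rii` is `NA` with
#'   a warning when a fitted rank extreme is not positive (ratio undefined).
#' @export
slope_and_relative_index <- function(values,
                                     ranks = seq(0.1, 0.9, by = 0.2),
                                     shares = rep(0.2, 5)) {
  stopifnot(length(values) == 5L, length(ranks) == 5L, length(shares) == 5L,
            all(shares > 0))
  if (abs(sum(shares) - 1) > 1e-6) stop("shares must sum to 1", call. = FALSE)
  W <- sum(shares)
  rbar <- sum(shares * ranks) / W
  vbar <- sum(shares * values) / W
  slope <- sum(shares * (ranks - rbar) * (values - vbar)) /
    sum(shares * (ranks - rbar)^2)
  intercept <- vbar - slope * rbar
  f0 <- intercept
  f1 <- intercept + slope
  rii <- if (f0 > 0 && f1 > 0) f1 / f0 else {
    # identity-link extrapolation can leave the positive orthant under
    # steep gradients; the ratio is then not a relative index
    warning("fitted value at a rank extreme is not positive; RII undefined",
            call. = FALSE)
    NA_real_
  }
  list(sii = slope, rii = rii, fitted0 = f0, fitted1 = f1)
}

#' SII/RII with credible intervals from posterior draws
#'
#' Applies [slope_and_relative_index()] to each joint posterior draw of the
#' five quintile values and summarizes by the mean and 2.5/97.5 percentiles.
#' Draws must be jointly indexed (row d of every quintile column comes from
#' the same posterior draw); permuting rows within a quintile would destroy
#' the posterior dependence between quintiles.
#'
#' @param draws_by_quintile Numeric matrix (draws x 5), or data frame, of
#'   quintile outcome draws in percent (columns Q1..Q5).
#' @param ranks,shares As in [slope_and_relative_index()].
#' @return Tibble with one row: `sii`, `sii_lo`, `sii_hi`, `rii`, `rii_lo`,
#'   `rii_hi` (RII summaries over draws with fitted(0) > 0).
#' @export
inequality_from_draws <- function(draws_by_quintile,
                                  ranks = seq(0.1, 0.9, by = 0.2),
                                  shares = rep(0.2, 5)) {
  X <- as.matrix(draws_by_quintile)
  if (ncol(X) != 5L) stop("need draws for exactly 5 quintiles", call. = FALSE)
  if (any(is.na(X))) stop("missing draws", call. = FALSE)

  # closed-form WLS per draw, vectorized over draws
  W <- sum(shares)
  rbar <- sum(shares * ranks) / W
  vbar <- as.vector(X %*% shares) / W
  sxx <- sum(shares * (ranks - rbar)^2)
  slope <- as.vector(X %*% (shares * (ranks - rbar))) / sxx -
    vbar * sum(shares * (ranks - rbar)) / sxx   # second term is 0 by centering
  f0 <- vbar - slope * rbar
  f1 <- f0 + slope
  rii <- ifelse(f0 > 0 & f1 > 0, f1 / f0, NA_real_)

  qs <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(c(NA_real_, NA_real_))
    stats::quantile(x, c(0.025, 0.975), names = FALSE)
  }
  s_q <- qs(slope); r_q <- qs(rii)
  tibble::tibble(sii = mean(slope), sii_lo = s_q[1], sii_hi = s_q[2],
                 rii = mean(rii, na.rm = TRUE), rii_lo = r_q[1], rii_hi = r_q[2])
}
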