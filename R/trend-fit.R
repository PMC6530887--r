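#' Assemble trend data on the logit scale
#'
#' All coverage and hardship trends are modelled on the log-odds scale:
#' `y_i = logit(p_i)` is regressed on calendar year with Gaussian errors and
#' a non-informative (flat) prior. Proportions must lie strictly inside
#' (0,1); boundary estimates should be continuity-adjusted upstream (see
#' [adjust_boundary()]).
#'
#' @param year Calendar years of the observed surveys.
#' @param p Observed proportions in (0,1).
#' @param group Optional group labels (wealth quintiles, regions).
#' @return A tibble of class `uhc_trend_data` with columns `year`, `p`, `y`
#'   and optionally `group`.
#' @export
trend_data <- function(year, p, group = NULL) {
  stopifnot(length(year) == length(p))
  ok <- !is.na(p)
  year <- year[ok]; p <- p[ok]
  if (!is.null(group)) group <- group[ok]
  if (length(unique(year)) < 3L && is.null(group)) {
    stop("need at least 3 distinct survey years for a trend", call. = FALSE)
  }
  d <- tibble::tibble(year = as.numeric(year), p = p, y = logit(p))
  if (!is.null(group)) d$group <- as.character(group)
  class(d) <- c("uhc_trend_data", class(d))
  d
}

#' Continuity adjustment for boundary proportions
#'
#' Maps an estimate of exactly 0 or 1 to `(p * n + 0.5) / (n + 1)` (a
#' half-success adjustment at the effective sample size) so the logit stays
#' finite; interior proportions are returned unchanged.
#'
#' @param p Proportions in `[0, 1]`.
#' @param n_eff Effective sample sizes.
#' @return Adjusted proportions strictly inside (0, 1).
#' @export
adjust_boundary <- function(p, n_eff) {
  ifelse(!is.na(p) & (p <= 0 | p >= 1), (p * n_eff + 0.5) / (n_eff + 1), p)
}

# Design matrix for the (optionally grouped) logit-linear trend.
# Year is centered at the first observed year for conditioning; the first
# group label alphabetically is the reference.
trend_design <- function(data, interaction = FALSE) {
  t0 <- min(data$year)
  t <- data$year - t0
  X <- cbind(alpha = 1, beta = t)
  groups <- NULL
  if ("group" %in% names(data)) {
    groups <- sort(unique(data$group))
    counts <- table(data$group)
    if (any(counts < 2L)) {
      stop("group(s) with a single observation: ",
           paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)
    }
    for (g in groups[-1L]) {
      X <- cbind(X, as.numeric(data$group == g))
      colnames(X)[ncol(X)] <- paste0("g_", g)
    }
    if (interaction && length(groups) > 1L) {
      for (g in groups[-1L]) {
        X <- cbind(X, as.numeric(data$group == g) * t)
        colnames(X)[ncol(X)] <- paste0("gb_", g)
      }
    }
  }
  list(X = X, y = data$y, t0 = t0, groups = groups, interaction = interaction)
}

new_uhc_draws <- function(draws, design, method, converged, psrf, n_iter) {
  structure(list(draws = draws, X = design$X, y = design$y, t0 = design$t0,
                 groups = design$groups, interaction = design$interaction,
                 method = method, converged = converged, psrf = psrf,
                 n_iter = n_iter),
            class = "uhc_draws")
}

#' @export
print.uhc_draws <- function(x, ...) {
  cat("<uhc_draws>", nrow(x$draws), "draws,", length(unique(x$draws$chain)),
      "chain(s), method:", x$method,
      if (isTRUE(x$converged)) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

# minimum residual variance kept on the logit scale for exact-line data
SIGMA2_FLOOR <- 1e-8

lstsq <- function(X, y) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("trend design matrix is rank deficient", call. = FALSE)
  bhat <- qr.coef(qrX, y)
  rss <- sum((y - X %*% bhat)^2)
  list(bhat = bhat, rss = rss, R = qr.R(qrX)[, , drop = FALSE])
}

#' Exact conjugate posterior for the logit-linear trend (analytic oracle)
#'
#' Under the flat prior `p(b, sigma^2) ~ 1/sigma^2` the posterior of the
#' Gaussian linear model is normal-inverse-gamma in closed form:
#' `sigma^2 | y` is scaled-inverse-chi-square with `n - p` degrees of freedom
#' around the residual mean square, and `b | sigma^2, y` is normal around the
#' least-squares solution with covariance `sigma^2 (X'X)^-1`. Draws are
#' sampled exactly from this joint (no Markov chain), which makes this fit
#' the independent oracle for the MCMC sampler.
#'
#' @param data A `uhc_trend_data` (optionally grouped).
#' @param n_draws Number of exact posterior draws (default 1000).
#' @param seed Integer seed.
#' @param interaction For grouped data, include group-specific slopes.
#' @return An object of class `uhc_draws`.
#' @export
fit_trend_conjugate <- function(data, n_draws = 1000, seed = 1L,
                                interaction = FALSE) {
  des <- trend_design(data, interaction)
  n <- length(des$y); p <- ncol(des$X)
  if (n - p < 1L) stop("need at least ", p + 1L,
                       " observations for a proper posterior", call. = FALSE)
  ls <- lstsq(des$X, des$y)
  rss <- ls$rss
  if (rss < SIGMA2_FLOOR) {
    warning("near-zero residual variance; flooring at ", SIGMA2_FLOOR,
            call. = FALSE)
    rss <- SIGMA2_FLOOR
  }
  withr::with_seed(seed, {
    sigma2 <- rss / stats::rchisq(n_draws, df = n - p)
    Z <- matrix(stats::rnorm(n_draws * p), p, n_draws)
    B <- ls$bhat + backsolve(ls$R, Z) * rep(sqrt(sigma2), each = p)
  })
  B <- t(B)
  colnames(B) <- colnames(des$X)
  draws <- tibble::as_tibble(B)
  draws <- dplyr::bind_cols(tibble::tibble(chain = 1L, iter = seq_len(n_draws)),
                            draws)
  draws$sigma2 <- sigma2
  new_uhc_draws(draws, des, "conjugate", TRUE,
                stats::setNames(rep(1, p + 1L), c(colnames(des$X), "sigma2")),
                n_draws)
}

# One Gibbs chain. The full conditionals of the flat-prior Gaussian linear
# model are b | s2 ~ N(bhat, s2 (X'X)^-1) and s2 | b ~ RSS(b)/chisq(n).
# Writing b = bhat + sqrt(s2) R^-1 z gives RSS(b) = RSS_min + s2 * z'z, so
# the chain reduces to a scalar recursion in s2, with the z vectors kept for
# the retained coefficient draws.
gibbs_chain <- function(bhat, R, rss_min, n, p, burn_in, keep, sigma2_init) {
  s2 <- sigma2_init
  Zkeep <- matrix(NA_real_, p, keep)
  s2keep <- numeric(keep)
  total <- burn_in + keep
  for (it in seq_len(total)) {
    z <- stats::rnorm(p)
    if (it > burn_in) {
      k <- it - burn_in
      Zkeep[, k] <- z * sqrt(s2)
      s2keep[k] <- s2
    }
    rss_b <- rss_min + s2 * sum(z^2)
    s2 <- rss_b / stats::rchisq(1L, df = n)
  }
  B <- bhat + backsolve(R, Zkeep)
  list(B = B, sigma2 = s2keep)
}

#' Fit the logit-linear trend by MCMC (Gibbs sampling)
#'
#' Same model and prior as [fit_trend_conjugate()], sampled with a two-block
#' Gibbs sampler: coefficients given the residual variance, then the
#' residual variance given the coefficients. Two chains are started from
#' overdispersed residual-variance values, the first `burn_in` iterations of
#' each chain are discarded, and `retained` draws are kept in total across
#' chains. Convergence is declared when the potential scale reduction factor
#' (PSRF) of every parameter is at most 1.02; otherwise the burn-in is
#' doubled and the sampler rerun, up to `max_iter` iterations per chain, and
#' a failure to converge is flagged (never silently ignored).
#'
#' @inheritParams fit_trend_conjugate
#' @param chains Number of chains (default 2).
#' @param burn_in Discarded iterations per chain (default 5000).
#' @param retained Total retained draws across chains (default 1000).
#' @param max_iter Iteration cap per chain when auto-extending (default 2e5).
#' @return An object of class `uhc_draws` with a `converged` flag and
#'   per-parameter PSRF values.
#' @export
fit_trend_mcmc <- function(data, chains = 2L, burn_in = 5000L, retained = 1000L,
                           seed = 1L, max_iter = 200000L, interaction = FALSE) {
  stopifnot(chains >= 2L, retained >= chains)
  des <- trend_design(data, interaction)
  n <- length(des$y); p <- ncol(des$X)
  if (n - p < 1L) stop("need at least ", p + 1L,
                       " observations for a proper posterior", call. = FALSE)
  ls <- lstsq(des$X, des$y)
  rss <- max(ls$rss, SIGMA2_FLOOR)
  s2_ls <- rss / max(n - p, 1L)
  keep <- ceiling(retained / chains)
  disperse <- exp(seq(-1.8, 1.8, length.out = chains))  # overdispersed starts

  bi <- burn_in
  repeat {
    res <- withr::with_seed(seed, {
      lapply(seq_len(chains), function(ch) {
        gibbs_chain(ls$bhat, ls$R, rss, n, p, bi, keep, s2_ls * disperse[ch])
      })
    })
    par_mats <- c(
      lapply(seq_len(p), function(j) {
        vapply(res, function(r) r$B[j, ], numeric(keep))
      }),
      list(vapply(res, function(r) log(r$sigma2), numeric(keep)))
    )
    psrf_vals <- vapply(par_mats, psrf, numeric(1))
    names(psrf_vals) <- c(colnames(des$X), "sigma2")
    if (all(psrf_vals <= 1.02) || bi * 2L + keep > max_iter) break
    bi <- bi * 2L
  }

  draws <- dplyr::bind_rows(lapply(seq_len(chains), function(ch) {
    Bc <- t(res[[ch]]$B)
    colnames(Bc) <- colnames(des$X)
    d <- tibble::as_tibble(Bc)
    d <- dplyr::bind_cols(tibble::tibble(chain = ch, iter = seq_len(keep)), d)
    d$sigma2 <- res[[ch]]$sigma2
    d
  }))
  draws <- draws[seq_len(retained), , drop = FALSE]
  new_uhc_draws(draws, des, "mcmc", all(psrf_vals <= 1.02), psrf_vals,
                bi + keep)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' `PSRF = sqrt(((n-1)/n * W + B/n) / W)` with `W` the mean within-chain
#' variance and `B` = n x variance of the chain means. Values above 1.02 are
#' treated as convergence failure throughout the package. Degenerate chains
#' (`W = 0`) return 1.
#'
#' @param chains A numeric matrix with one column per chain (iterations in
#'   rows), or an `uhc_draws` object (returns the stored per-parameter
#'   values).
#' @return A scalar PSRF, or a named vector for `uhc_draws` input.
#' @export
psrf <- function(chains) {
  if (inherits(chains, "uhc_draws")) return(chains$psrf)
  X <- as.matrix(chains)
  n <- nrow(X); m <- ncol(X)
  stopifnot(n >= 2L, m >= 2L)
  W <- mean(apply(X, 2L, stats::var))
  if (W == 0) return(1)
  B <- n * stats::var(colMeans(X))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Deviance information criterion for a trend fit
#'
#' Deviance is `-2 x` the Gaussian log-likelihood on the logit scale.
#' `Dbar` is the posterior mean deviance, `pD = Dbar - D(thetabar)` the
#' effective number of parameters (deviance at the posterior means of the
#' coefficients and residual variance), and `DIC = Dbar + pD` the penalized
#' deviance; smaller is preferred.
#'
#' @param fit An `uhc_draws` object (carries its data and design).
#' @return List with `Dbar`, `pD`, `DIC`, `Dhat`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "uhc_draws"))
  p <- ncol(fit$X)
  B <- as.matrix(fit$draws[, colnames(fit$X), drop = FALSE])
  s2 <- fit$draws$sigma2
  mu <- fit$X %*% t(B)                       # n x draws
  dev <- vapply(seq_along(s2), function(d) {
    -2 * sum(stats::dnorm(fit$y, mu[, d], sqrt(s2[d]), log = TRUE))
  }, numeric(1))
  Dbar <- mean(dev)
  bbar <- colMeans(B); s2bar <- mean(s2)
  Dhat <- -2 * sum(stats::dnorm(fit$y, as.vector(fit$X %*% bbar), sqrt(s2bar),
                                log = TRUE))
  pD <- Dbar - Dhat
  list(Dbar = Dbar, pD = pD, DIC = Dbar + pD, Dhat = Dhat)
}

#' Fit a wealth-quintile (or region) adjusted trend
#'
#' Adds additive group intercept offsets to the logit-linear trend; with
#' `interaction = TRUE`, group-specific year slopes as well. The first group
#' label alphabetically is the reference. With a single group the model
#' reduces exactly to the ungrouped trend.
#'
#' @param data A grouped `uhc_trend_data` (column `group`).
#' @param interaction Include group x year interaction terms.
#' @param method `"mcmc"` (default) or `"conjugate"`.
#' @param chains,burn_in,max_iter MCMC settings, see [fit_trend_mcmc()];
#'   ignored by the conjugate sampler.
#' @param retained Retained draws (total across chains).
#' @param seed Integer seed.
#' @return An object of class `uhc_draws`.
#' @export
fit_grouped_trend <- function(data, interaction = FALSE,
                              method = c("mcmc", "conjugate"), chains = 2L,
                              burn_in = 5000L, retained = 1000L, seed = 1L,
                              max_iter = 200000L) {
  method <- match.arg(method)
  if (!"group" %in% names(data)) stop("data has no group column", call. = FALSE)
  if (method == "mcmc") {
    fit_trend_mcmc(data, chains = chains, burn_in = burn_in,
                   retained = retained, seed = seed, max_iter = max_iter,
                   interaction = interaction)
  } else {
    fit_trend_conjugate(data, n_draws = retained, seed = seed,
                        interaction = interaction)
  }
}

#' Choose between the interaction and no-interaction grouped models by DIC
#'
#' Fits the grouped trend with and without group x year interaction terms
#' and returns the model with the smaller penalized deviance, together with
#' both DIC values and convergence diagnostics. If either fit fails to
#' converge the selection is aborted and only the diagnostics are returned.
#'
#' @inheritParams fit_grouped_trend
#' @param ... Passed on to [fit_grouped_trend()] (chains, burn-in, retained
#'   draws, seed).
#' @return List with `model` (the chosen `uhc_draws`, or `NULL` if aborted),
#'   `interaction` (logical, chosen model), `dic` (named vector with both
#'   penalized deviances) and `diagnostics` (per-model PSRF and convergence
#'   flags).
#' @export
select_model_by_dic <- function(data, method = c("mcmc", "conjugate"), ...) {
  method <- match.arg(method)
  f0 <- fit_grouped_trend(data, interaction = FALSE, method = method, ...)
  f1 <- fit_grouped_trend(data, interaction = TRUE, method = method, ...)
  d0 <- dic(f0); d1 <- dic(f1)
  dics <- c(no_interaction = d0$DIC, interaction = d1$DIC)
  diag <- list(no_interaction = list(psrf = f0$psrf, converged = f0$converged),
               interaction = list(psrf = f1$psrf, converged = f1$converged))
  if (!isTRUE(f0$converged) || !isTRUE(f1$converged)) {
    return(list(model = NULL, interaction = NA, dic = dics, diagnostics = diag))
  }
  pick <- d1$DIC < d0$DIC
  list(model = if (pick) f1 else f0, interaction = pick, dic = dics,
       diagnostics = diag)
}
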