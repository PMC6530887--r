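#' Asset-based wealth index by principal components
#'
#' Classic DHS-style wealth index: each binary asset indicator is
#' standardized (weighted mean 0, weighted variance 1) and the household
#' score is the first principal component of the standardized asset matrix.
#' The sign is fixed so the score correlates positively with the raw asset
#' count, i.e. higher score = wealthier. Zero-variance assets are dropped
#' with a warning. The index is computed within a single survey year: each
#' survey carries its own index.
#'
#' @param microdata Coverage microdata containing `asset_*` columns,
#'   `weight`, and `year` (see [generate_coverage_microdata()]).
#' @param year Survey year to use.
#' @return A tibble with columns `year`, `row` (row index within the year's
#'   subset), `score`, `weight`. The proportion of standardized variance
#'   carried by the first component is attached as attribute `var_explained`.
#' @export
compute_wealth_index <- function(microdata, year) {
  d <- microdata[microdata$year == year, , drop = FALSE]
  if (nrow(d) == 0L) stop("no rows for year ", year, call. = FALSE)
  acols <- grep("^asset_", names(d), value = TRUE)
  if (length(acols) < 2L) stop("need at least two asset columns", call. = FALSE)
  A <- as.matrix(d[, acols])
  w <- d$weight

  keep <- apply(A, 2L, function(a) stats::var(a) > 0)
  if (!any(keep)) stop("all assets have zero variance; wealth index undefined",
                       call. = FALSE)
  if (any(!keep)) {
    warning("dropping zero-variance asset(s): ",
            paste(acols[!keep], collapse = ", "), call. = FALSE)
    A <- A[, keep, drop = FALSE]
  }

  wm <- colSums(A * w) / sum(w)
  wv <- colSums(sweep(A, 2L, wm)^2 * w) / sum(w)
  X <- sweep(sweep(A, 2L, wm), 2L, sqrt(wv), "/")

  # eigendecomposition of the (unweighted) second-moment matrix; columns of X
  # have weighted mean zero, so the score inherits weighted mean exactly zero
  S <- crossprod(X) / (nrow(X) - 1L)
  e <- eigen(S, symmetric = TRUE)
  v <- e$vectors[, 1L]
  score <- drop(X %*% v)
  if (stats::cor(score, rowSums(A)) < 0) score <- -score

  out <- tibble::tibble(year = year, row = seq_len(nrow(d)),
                        score = score, weight = w)
  attr(out, "var_explained") <- e$values[1L] / sum(pmax(e$values, 0))
  out
}

#' Assign population-weighted wealth quintiles
#'
#' Households are ranked by score (ties broken by stable input order) and
#' each is placed in the fifth of the cumulative population-weight
#' distribution that contains its weighted-rank midpoint. With equal weights
#' this reduces to cutting at the 20/40/60/80 weighted percentiles; a
#' household holding a large weight share is assigned to the quintile
#' containing its midpoint. Q1 is the poorest quintile.
#'
#' @param score Numeric wealth scores (or any monotone welfare measure).
#' @param weight Positive sampling weights.
#' @return An object of class `uhc_quintiles`: list with `quintile` (integer
#'   1-5 per household, input order), `rel_rank` (each household's
#'   weighted-rank midpoint in (0,1)), `shares` (realized weighted share of
#'   each quintile) and `midpoints` (per-quintile relative-rank midpoints,
#'   see [quintile_relative_ranks()]).
#' @export
assign_quintiles <- function(score, weight) {
  stopifnot(length(score) == length(weight), all(weight > 0), !any(is.na(score)))
  if (length(unique(score)) < 5L) {
    stop("fewer than 5 distinct scores; quintiles are degenerate", call. = FALSE)
  }
  ord <- order(score)                       # stable for ties (radix)
  w <- weight[ord] / sum(weight)
  cw <- cumsum(w)
  mid <- cw - w / 2                         # weighted-rank midpoint per household
  q_sorted <- as.integer(pmin(5, floor(mid * 5) + 1))
  quintile <- integer(length(score))
  quintile[ord] <- q_sorted
  rel_rank <- numeric(length(score))
  rel_rank[ord] <- mid

  shares <- vapply(1:5, function(q) sum(weight[quintile == q]) / sum(weight),
                   numeric(1))
  structure(list(quintile = quintile, rel_rank = rel_rank, shares = shares,
                 midpoints = cumsum(shares) - shares / 2),
            class = "uhc_quintiles")
}

#' Relative-rank midpoints of wealth quintiles
#'
#' For quintile q occupying the cumulative weighted-share interval
#' `[c_{q-1}, c_q]`, the relative rank (ridit) midpoint is
#' `(c_{q-1} + c_q) / 2`. These are the abscissae of the SII/RII regression.
#'
#' @param assignment An `uhc_quintiles` object, or a numeric vector of 5
#'   quintile population shares summing to 1.
#' @return Numeric vector of 5 strictly increasing midpoints in (0,1).
#' @export
quintile_relative_ranks <- function(assignment) {
  shares <- if (inherits(assignment, "uhc_quintiles")) assignment$shares
            else assignment
  stopifnot(length(shares) == 5L, abs(sum(shares) - 1) < 1e-8)
  if (any(shares <= 0)) {
    stop("empty quintile: rank midpoints undefined", call. = FALSE)
  }
  cumsum(shares) - shares / 2
}

#' Attach wealth columns to coverage microdata
#'
#' Convenience wrapper running [compute_wealth_index()] and
#' [assign_quintiles()] per survey year and adding `wealth_score`,
#' `quintile` and `rel_rank` columns.
#'
#' @param microdata Coverage microdata.
#' @return The microdata with three added columns.
#' @export
add_wealth_quintiles <- function(microdata) {
  parts <- lapply(sort(unique(microdata$year)), function(yr) {
    d <- microdata[microdata$year == yr, , drop = FALSE]
    ws <- compute_wealth_index(microdata, yr)
    qa <- assign_quintiles(ws$score, ws$weight)
    d$wealth_score <- ws$score
    d$quintile <- qa$quintile
    d$rel_rank <- qa$rel_rank
    d
  })
  dplyr::bind_rows(parts)
}
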