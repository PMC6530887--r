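#' Logit and inverse-logit transforms
#'
#' The log-odds transform maps a proportion in (0,1) to the real line; all
#' trend modelling in this package happens on the logit scale.
#'
#' @param p Numeric vector of proportions, strictly inside (0,1).
#' @param y Numeric vector on the log-odds scale.
#' @return `logit()` returns log(p/(1-p)); `inv_logit()` its inverse.
#' @examples
#' logit(0.5)            # 0
#' inv_logit(logit(0.8)) # 0.8
#' @export
logit <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("logit() requires proportions strictly inside (0, 1); ",
         "apply a boundary adjustment upstream", call. = FALSE)
  }
  log(p / (1 - p))
}

#' @rdname logit
#' @export
inv_logit <- function(y) stats::plogis(y)

#' Weighted quantile (inverse-CDF, lower-inclusive)
#'
#' Step-function weighted quantile: the smallest observed value whose
#' cumulative weight share reaches `probs`. This definition is deterministic
#' across implementations and is used for the poverty-line food-share band
#' and wealth-quintile cut points.
#'
#' @param x Numeric values.
#' @param w Positive weights, same length as `x`.
#' @param probs Probabilities in `[0,1]`.
#' @return Numeric vector of quantiles, one per element of `probs`.
#' @export
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w > 0), all(probs >= 0), all(probs <= 1))
  ok <- !is.na(x)
  x <- x[ok]; w <- w[ok]
  if (length(x) == 0L) stop("weighted_quantile(): no non-missing values", call. = FALSE)
  ord <- order(x)
  x <- x[ord]
  cw <- cumsum(w[ord]) / sum(w)
  vapply(probs, function(p) {
    if (p <= 0) return(x[1L])
    x[which(cw >= p - 1e-12)[1L]]
  }, numeric(1))
}

#' Weighted mean dropping missing values
#' @noRd
wmean <- function(x, w) {
  ok <- !is.na(x)
  sum(x[ok] * w[ok]) / sum(w[ok])
}

#' Derive a child RNG seed from a base seed
#'
#' Keeps derived seeds inside the 32-bit integer range so they are valid
#' arguments to `set.seed()`.
#' @noRd
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}
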