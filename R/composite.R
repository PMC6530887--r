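#' DerSimonian-Laird random-effects pooling
#'
#' Pools indicator-level estimates (on the percent scale by default) into a
#' composite index using the classic DerSimonian-Laird moment estimator of
#' the between-indicator variance: fixed-effect weights `w_i = 1/SE_i^2`,
#' heterogeneity `Q = sum w_i (y_i - ybar_w)^2`, `tau^2 = max(0, (Q - (k-1)) /
#' (sum w - sum w^2 / sum w))`, then random-effects weights
#' `1 / (SE_i^2 + tau^2)`.
#'
#' With equal standard errors the pooled value is the arithmetic mean of the
#' inputs, matching the reading of a composite index as a mean of its
#' component indicators.
#'
#' @param values Numeric estimates (e.g. coverage in percent).
#' @param ses Positive standard errors, same length.
#' @param scale `"percent"` (default) pools the values as given; `"logit"`
#'   pools on the log-odds scale (values interpreted as percents in (0,100))
#'   and back-transforms, with delta-method SEs.
#' @return List with `pooled`, `se`, `tau2`, `ci_lo`, `ci_hi`, `k`.
#' @export
pool_random_effects <- function(values, ses, scale = c("percent", "logit")) {
  scale <- match.arg(scale)
  stopifnot(length(values) == length(ses), length(values) >= 1)
  if (any(is.na(values)) || any(is.na(ses))) stop("missing inputs", call. = FALSE)
  if (any(ses <= 0)) stop("standard errors must be positive", call. = FALSE)

  if (scale == "logit") {
    p <- values / 100
    y <- logit(p)
    s <- ses / 100 / (p * (1 - p))
    dl <- dl_pool(y, s)
    pl <- inv_logit(dl$pooled); der <- pl * (1 - pl)
    return(list(pooled = 100 * pl, se = 100 * der * dl$se, tau2 = dl$tau2,
                ci_lo = 100 * inv_logit(dl$pooled - 1.959964 * dl$se),
                ci_hi = 100 * inv_logit(dl$pooled + 1.959964 * dl$se),
                k = dl$k))
  }
  dl_pool(values, ses)
}

dl_pool <- function(y, s) {
  k <- length(y)
  if (k == 1L) {
    return(list(pooled = y, se = s, tau2 = 0,
                ci_lo = y - 1.959964 * s, ci_hi = y + 1.959964 * s, k = 1L))
  }
  w <- 1 / s^2
  ybar <- sum(w * y) / sum(w)
  Q <- sum(w * (y - ybar)^2)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (s^2 + tau2)
  pooled <- sum(wr * y) / sum(wr)
  se <- sqrt(1 / sum(wr))
  list(pooled = pooled, se = se, tau2 = tau2,
       ci_lo = pooled - 1.959964 * se, ci_hi = pooled + 1.959964 * se, k = k)
}

#' Composite coverage index (CCI)
#'
#' Weighted mean of eight reproductive, maternal and child health
#' interventions across four specialty areas, each area carrying a quarter of
#' the weight: family planning (needs satisfied); maternal and newborn care
#' (skilled birth attendance and four antenatal visits, split equally);
#' immunization (DPT3 double-weighted alongside measles and BCG); and case
#' management of childhood illness (oral rehydration therapy and care
#' seeking for pneumonia, split equally):
#'
#' `CCI = 1/4 * (fps + (sba + anc)/2 + (2*dpt3 + msl + bcg)/4 + (ort + carep)/2)`
#'
#' @param fps,anc,sba,bcg,dpt3,msl,ort,carep Coverage percents in `[0,100]`.
#' @return CCI in percent. Monotone non-decreasing in every argument.
#' @examples
#' composite_coverage_index(80, 80, 80, 80, 80, 80, 80, 80)  # 80
#' @export
composite_coverage_index <- function(fps, anc, sba, bcg, dpt3, msl, ort, carep) {
  x <- c(fps = fps, anc = anc, sba = sba, bcg = bcg, dpt3 = dpt3, msl = msl,
         ort = ort, carep = carep)
  if (any(is.na(x)) || any(x < 0) || any(x > 100)) {
    stop("all CCI inputs must lie in [0, 100]", call. = FALSE)
  }
  (fps + (sba + anc) / 2 + (2 * dpt3 + msl + bcg) / 4 + (ort + carep) / 2) / 4
}

#' Composite prevention/treatment indices for a table of estimates
#'
#' Pools the registry's composite-flagged prevention indicators and all
#' treatment indicators per year x group via [pool_random_effects()], and
#' evaluates the CCI from the eight point estimates where all are present.
#'
#' @param estimates Output of [estimate_all()] (proportions in `[0,1]`).
#' @param registry Indicator registry.
#' @param scale Pooling scale, see [pool_random_effects()].
#' @return Tibble: `label` (prevention/treatment/cci), `year`, `group_type`,
#'   `group`, `value` (percent), `se`, `ci_lo`, `ci_hi`, `tau2`, `k`.
#' @export
composite_indices <- function(estimates, registry = default_indicator_registry(),
                              scale = "percent") {
  prev <- registry$name[registry$class == "prevention" & registry$in_composite]
  trt <- registry$name[registry$class == "treatment"]
  cci_args <- c(fps = "fps", anc = "anc4", sba = "sba", bcg = "bcg",
                dpt3 = "dpt3", msl = "measles", ort = "ort", carep = "carep")
  cells <- unique(estimates[, c("year", "group_type", "group")])
  out <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    d <- dplyr::semi_join(estimates, cell, by = c("year", "group_type", "group"))
    d <- d[!is.na(d$p_hat) & !is.na(d$se) & d$se > 0, , drop = FALSE]
    for (lab in c("prevention", "treatment")) {
      nms <- if (lab == "prevention") prev else trt
      dd <- d[d$indicator %in% nms, , drop = FALSE]
      if (nrow(dd) == 0L) next
      pl <- pool_random_effects(100 * dd$p_hat, 100 * dd$se, scale = scale)
      out[[length(out) + 1L]] <- tibble::tibble(
        label = lab, year = cell$year, group_type = cell$group_type,
        group = cell$group, value = pl$pooled, se = pl$se,
        ci_lo = pl$ci_lo, ci_hi = pl$ci_hi, tau2 = pl$tau2, k = pl$k)
    }
    if (all(cci_args %in% d$indicator)) {
      v <- vapply(cci_args, function(nm) 100 * d$p_hat[d$indicator == nm][1],
                  numeric(1))
      out[[length(out) + 1L]] <- tibble::tibble(
        label = "cci", year = cell$year, group_type = cell$group_type,
        group = cell$group, value = do.call(composite_coverage_index,
                                            as.list(unname(v))),
        se = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
        tau2 = NA_real_, k = 8L)
    }
  }
  dplyr::bind_rows(out)
}
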