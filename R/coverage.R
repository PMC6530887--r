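#' Default health-service indicator registry
#'
#' Seventeen indicators: thirteen prevention services and four treatment
#' services. Nine prevention indicators (four or more antenatal care visits,
#' exclusive breastfeeding, family-planning needs satisfied, improved water,
#' adequate sanitation, and BCG/measles/DPT3/Polio3 immunization) enter the
#' composite prevention index; all four treatment indicators enter the
#' composite treatment index. The coverage target is 80% for every indicator.
#'
#' @return A tibble with columns `name`, `label`, `class`
#'   (prevention/treatment), `in_composite`, `target`, `denominator`.
#' @export
default_indicator_registry <- function() {
  reg <- tibble::tribble(
    ~name,            ~label,                                    ~class,       ~in_composite,
    "fps",            "Needs for family planning satisfied",     "prevention", TRUE,
    "anc4",           "At least four antenatal care visits",     "prevention", TRUE,
    "pnc_mothers",    "Postnatal care for mothers",              "prevention", FALSE,
    "ebf",            "Exclusive breastfeeding",                 "prevention", TRUE,
    "itn_children",   "Insecticide treated bed nets for children","prevention", FALSE,
    "itn_mothers",    "Insecticide treated bed nets for mothers","prevention", FALSE,
    "bcg",            "BCG immunization",                        "prevention", TRUE,
    "dpt3",           "DPT3 immunization",                       "prevention", TRUE,
    "polio3",         "Polio3 immunization",                     "prevention", TRUE,
    "measles",        "Measles immunization",                    "prevention", TRUE,
    "improved_water", "Improved water",                          "prevention", TRUE,
    "sanitation",     "Adequate sanitation",                     "prevention", TRUE,
    "no_tobacco",     "No-use of tobacco",                       "prevention", FALSE,
    "inst_delivery",  "Institutional delivery",                  "treatment",  TRUE,
    "sba",            "Skilled birth attendance",                "treatment",  TRUE,
    "ort",            "Oral rehydration therapy",                "treatment",  TRUE,
    "carep",          "Care seeking for pneumonia",              "treatment",  TRUE
  )
  reg$target <- 0.80
  reg$denominator <- "all"   # row-level eligibility: non-missing outcome
  reg
}

# Survey-weighted proportion with cluster-linearized (Taylor) variance.
# Clusters are the primary sampling units; the score residuals w*(y - p)
# are totalled per cluster and their between-cluster variability estimates
# the design-based variance of the ratio estimator.
svy_prop <- function(y, w, cluster) {
  ok <- !is.na(y)
  y <- y[ok]; w <- w[ok]; cluster <- cluster[ok]
  n <- length(y)
  if (n == 0L) {
    return(list(p = NA_real_, se = NA_real_, lo = NA_real_, hi = NA_real_,
                n_eff = 0, n = 0L))
  }
  W <- sum(w)
  p <- sum(w * y) / W
  n_eff <- W^2 / sum(w^2)

  z <- tapply(w * (y - p), cluster, sum)     # cluster totals; they sum to 0
  m <- length(z)
  se <- if (m > 1L) sqrt(m / (m - 1) * sum(z^2)) / W else NA_real_

  # CI on the logit scale, back-transformed; boundary estimates get a
  # half-success continuity adjustment so the logit stays finite
  p_ci <- p
  se_ci <- se
  if (!is.na(p) && (p <= 0 || p >= 1)) {
    p_ci <- (p * n_eff + 0.5) / (n_eff + 1)
    se_ci <- sqrt(p_ci * (1 - p_ci) / n_eff)
  }
  if (!is.na(se_ci) && se_ci > 0 && p_ci > 0 && p_ci < 1) {
    l <- logit(p_ci)
    sl <- se_ci / (p_ci * (1 - p_ci))
    lo <- inv_logit(l - stats::qnorm(0.975) * sl)
    hi <- inv_logit(l + stats::qnorm(0.975) * sl)
  } else if (!is.na(se_ci) && se_ci == 0) {
    lo <- hi <- p
  } else {
    lo <- hi <- NA_real_
  }
  list(p = p, se = se, lo = lo, hi = hi, n_eff = n_eff, n = n)
}

#' Estimate a survey-weighted coverage proportion
#'
#' Point estimate is the weighted mean of the binary outcome over eligible
#' (non-missing) rows; the standard error comes from cluster-level Taylor
#' linearization with clusters as primary sampling units within the year,
#' and the 95% confidence interval is computed on the logit scale and
#' back-transformed (boundary proportions get a half-success continuity
#' adjustment before the logit).
#'
#' @param microdata Coverage microdata (see [generate_coverage_microdata()]),
#'   optionally pre-filtered to a subgroup.
#' @param indicator Indicator name (an `outcome_<indicator>` column).
#' @param year Survey year.
#' @return One-row tibble: `indicator`, `year`, `p_hat`, `se`, `ci_lo`,
#'   `ci_hi`, `n_eff`, `n`. An empty denominator yields a flagged row with
#'   missing `p_hat`, never a silent zero.
#' @export
estimate_proportion <- function(microdata, indicator, year) {
  col <- paste0("outcome_", indicator)
  if (!col %in% names(microdata)) stop("unknown indicator: ", indicator, call. = FALSE)
  d <- microdata[microdata$year == year, , drop = FALSE]
  r <- svy_prop(d[[col]], d$weight, d$cluster_id)
  tibble::tibble(indicator = indicator, year = year, p_hat = r$p, se = r$se,
                 ci_lo = r$lo, ci_hi = r$hi, n_eff = r$n_eff, n = r$n)
}

#' Estimate coverage for every indicator, year and grouping
#'
#' Applies [estimate_proportion()] over the cross-product of registry
#' indicators, survey years, and the requested groupings (`"national"`,
#' `"quintile"`, `"region"`). Quintile groups use the year-specific wealth
#' index from [add_wealth_quintiles()] (computed here if the columns are
#' absent). Indicator-years with no data are emitted as flagged rows with
#' missing estimates.
#'
#' @param microdata Coverage microdata.
#' @param registry Indicator registry, default [default_indicator_registry()];
#'   indicators without a matching outcome column are skipped.
#' @param groupings Character subset of `c("national", "quintile", "region")`.
#' @return Tibble: `indicator`, `class`, `year`, `group_type`, `group`,
#'   `p_hat`, `se`, `ci_lo`, `ci_hi`, `n_eff`, `n`.
#' @export
estimate_all <- function(microdata, registry = default_indicator_registry(),
                         groupings = "national") {
  stopifnot(all(groupings %in% c("national", "quintile", "region")))
  have <- sub("^outcome_", "", grep("^outcome_", names(microdata), value = TRUE))
  missing_ind <- setdiff(registry$name, have)
  if (length(missing_ind) == length(registry$name)) {
    stop("no registry indicator has an outcome column", call. = FALSE)
  }
  registry <- registry[registry$name %in% have, , drop = FALSE]

  if ("quintile" %in% groupings && !"quintile" %in% names(microdata)) {
    microdata <- add_wealth_quintiles(microdata)
  }
  years <- sort(unique(microdata$year))

  one <- function(d, ind, yr, gtype, glab) {
    est <- estimate_proportion(d, ind, yr)
    est$group_type <- gtype
    est$group <- as.character(glab)
    est
  }
  res <- list()
  for (ind in registry$name) {
    for (yr in years) {
      if ("national" %in% groupings) {
        res[[length(res) + 1L]] <- one(microdata, ind, yr, "national", "national")
      }
      if ("quintile" %in% groupings) {
        for (q in 1:5) {
          res[[length(res) + 1L]] <-
            one(microdata[microdata$quintile == q, ], ind, yr, "quintile",
                paste0("Q", q))
        }
      }
      if ("region" %in% groupings) {
        for (g in sort(unique(microdata$region_id))) {
          res[[length(res) + 1L]] <-
            one(microdata[microdata$region_id == g, ], ind, yr, "region", g)
        }
      }
    }
  }
  out <- dplyr::bind_rows(res)
  out <- dplyr::left_join(out, registry[, c("name", "class")],
                          by = c(indicator = "name"))
  dplyr::select(out, "indicator", "class", "year", "group_type", "group",
                "p_hat", "se", "ci_lo", "ci_hi", "n_eff", "n")
}
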