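#' Default per-indicator generating parameters
#'
#' One entry per health-service indicator in the default registry. Each entry
#' has a logit-scale intercept `a0` (at the first survey year), a year slope
#' `b` (logit units per calendar year), a wealth gradient `g` (logit units per
#' standard deviation of latent wealth), and optionally `start_year`, the
#' first calendar year for which the survey instrument carried the item
#' (outcomes before it are missing, mirroring indicators that entered the
#' survey programme late).
#'
#' The magnitudes mimic the published Ghanaian trajectories of these
#' indicators (e.g. near-universal childhood immunization by 2015, steeply
#' rising bed-net use after 2003, a large wealth gradient for sanitation and
#' institutional delivery).
#'
#' @return Named list of per-indicator parameter lists.
#' @export
default_indicator_params <- function() {
  p <- function(a0, b, g, start_year = NA_real_) {
    list(a0 = a0, b = b, g = g, start_year = start_year)
  }
  list(
    fps            = p(-0.55, 0.020, 0.25),
    anc4           = p( 0.30, 0.069, 0.50),
    pnc_mothers    = p(-6.10, 0.330, 0.40, start_year = 2003),
    ebf            = p(-1.60, 0.118, 0.10),
    itn_children   = p(-5.06, 0.243, 0.15, start_year = 2003),
    itn_mothers    = p(-5.85, 0.268, 0.15, start_year = 2003),
    bcg            = p( 1.73, 0.088, 0.35),
    dpt3           = p( 0.73, 0.077, 0.40),
    polio3         = p( 0.75, 0.058, 0.40),
    measles        = p( 0.82, 0.079, 0.40),
    improved_water = p( 0.44, 0.073, 0.60),
    sanitation     = p(-1.12, 0.084, 1.20),
    no_tobacco     = p( 2.40, -0.010, 0.15, start_year = 2003),
    inst_delivery  = p(-0.39, 0.064, 1.00),
    sba            = p(-0.35, 0.063, 0.90),
    ort            = p(-0.43, 0.062, 0.25),
    carep          = p(-0.58, 0.028, 0.35)
  )
}

#' Default region effects and names
#'
#' Additive logit offsets for the ten administrative regions; one markedly
#' negative region emulates the persistently lagging Northern region.
#' @param n_regions Number of regions.
#' @return Numeric vector of logit offsets, named when `n_regions == 10`.
#' @export
default_region_effects <- function(n_regions = 10) {
  eff <- c(0.15, 0.05, -0.10, 0.10, 0.35, -0.50, 0.20, 0.25, 0.00, -0.05)
  nm <- c("Ashanti", "Brong-Ahafo", "Central", "Eastern", "Greater Accra",
          "Northern", "Upper East", "Upper West", "Volta", "Western")
  if (n_regions == 10L || n_regions == 10) {
    stats::setNames(eff, nm)
  } else {
    rep_len(eff, n_regions)
  }
}

#' Default expenditure-survey generating parameters
#'
#' Four consumption-survey waves with log-normal per-capita total
#' expenditure, a food share declining across waves (households spend
#' relatively more on non-food items over time), and a zero-inflated
#' log-normal out-of-pocket (OOP) health spending model whose location drifts
#' down relative to non-food spending, so catastrophic-expenditure incidence
#' declines across waves from roughly 15% to a few percent.
#'
#' @return List of expenditure generating parameters.
#' @export
default_expenditure_params <- function() {
  list(
    survey_years     = c(1991, 1998, 2005, 2012),
    n_households     = 3000,
    log_mean_pc      = log(800),
    log_mean_drift   = 0.04,
    log_sd_pc        = 0.65,
    mean_food_share  = c(0.62, 0.58, 0.52, 0.46),
    food_share_sd    = 0.5,
    mean_hh_size     = 4.3,
    p_any_oop        = 0.65,
    oop_log_mean     = c(4.70, 4.56, 4.48, 4.37),
    oop_log_sd       = 1.2,
    region_oop_effects = c(0.10, 0.00, 0.20, 0.05, -0.30, -0.05, -0.30,
                           -0.35, 0.12, -0.02)
  )
}

#' Build a synthetic survey configuration
#'
#' Bundles every generating parameter of the synthetic DHS-like coverage
#' survey and GLSS-like expenditure survey into a validated configuration
#' object. The defaults define the package's reference scenario: five
#' coverage survey waves (1993-2014), two-stage cluster samples with
#' sampling weights, ten regions, ten binary asset indicators driven by a
#' latent wealth factor with intra-cluster correlation, and four expenditure
#' waves with declining catastrophic-spending risk.
#'
#' @param survey_years Strictly increasing calendar years of the coverage
#'   survey waves.
#' @param n_clusters Clusters (primary sampling units) per survey year.
#' @param households_per_cluster Households sampled per cluster.
#' @param n_regions Number of administrative regions.
#' @param n_assets Number of binary asset indicators.
#' @param wealth_icc Share of latent-wealth variance at the cluster level
#'   (intra-cluster correlation); latent wealth is standard normal marginally.
#' @param weight_cv Coefficient of variation of the sampling weights
#'   (log-normal, normalized so weights sum to the sample size per year).
#' @param missing_rate Probability that an eligible outcome is missing.
#' @param indicator_params Named list of per-indicator generating parameters,
#'   see [default_indicator_params()].
#' @param region_effects Additive logit offsets per region.
#' @param expenditure_params See [default_expenditure_params()].
#' @param seed Integer seed; all generation is reproducible given the config.
#' @return An object of class `uhc_config` (a named list).
#' @export
synthetic_config <- function(survey_years = c(1993, 1998, 2003, 2008, 2014),
                             n_clusters = 100,
                             households_per_cluster = 20,
                             n_regions = 10,
                             n_assets = 10,
                             wealth_icc = 0.3,
                             weight_cv = 0.25,
                             missing_rate = 0,
                             indicator_params = default_indicator_params(),
                             region_effects = default_region_effects(n_regions),
                             expenditure_params = default_expenditure_params(),
                             seed = 20301L) {
  cfg <- structure(
    list(survey_years = as.numeric(survey_years),
         n_clusters = as.integer(n_clusters),
         households_per_cluster = as.integer(households_per_cluster),
         n_regions = as.integer(n_regions),
         n_assets = as.integer(n_assets),
         wealth_icc = wealth_icc,
         weight_cv = weight_cv,
         missing_rate = missing_rate,
         indicator_params = indicator_params,
         region_effects = region_effects,
         expenditure_params = expenditure_params,
         seed = as.integer(seed)),
    class = "uhc_config"
  )
  validate_config(cfg)
  cfg
}

#' Validate a synthetic survey configuration
#' @param config An `uhc_config` object.
#' @return The config, invisibly, or an error describing the violation.
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config))
  with(config, {
    if (any(diff(survey_years) <= 0) || length(survey_years) < 1) {
      stop("survey_years must be strictly increasing", call. = FALSE)
    }
    if (n_clusters <= 0 || households_per_cluster <= 0 ||
        n_regions <= 0 || n_assets <= 0) {
      stop("all counts must be positive", call. = FALSE)
    }
    if (wealth_icc < 0 || wealth_icc >= 1) stop("wealth_icc must be in [0,1)", call. = FALSE)
    if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0,1)", call. = FALSE)
    if (length(region_effects) != n_regions) {
      stop("region_effects must have one entry per region", call. = FALSE)
    }
    for (nm in names(indicator_params)) {
      ip <- indicator_params[[nm]]
      if (!all(c("a0", "b", "g") %in% names(ip))) {
        stop("indicator_params[['", nm, "']] needs fields a0, b, g", call. = FALSE)
      }
    }
    ep <- expenditure_params
    if (any(diff(ep$survey_years) <= 0)) {
      stop("expenditure survey_years must be strictly increasing", call. = FALSE)
    }
    if (any(ep$mean_food_share <= 0) || any(ep$mean_food_share >= 1)) {
      stop("mean_food_share must lie in (0,1)", call. = FALSE)
    }
    if (ep$log_sd_pc <= 0 || ep$oop_log_sd <= 0 || ep$food_share_sd <= 0) {
      stop("sd parameters must be positive", call. = FALSE)
    }
    if (ep$p_any_oop < 0 || ep$p_any_oop > 1) {
      stop("p_any_oop must be a probability", call. = FALSE)
    }
  })
  invisible(config)
}

# Asset response model: item j has its own difficulty and loading so the
# asset battery spans the wealth distribution.
asset_cuts <- function(K) seq(-1.2, 1.2, length.out = K)
asset_loadings <- function(K) seq(0.8, 1.6, length.out = K)

# log-normal sdlog giving a target coefficient of variation
cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

#' Generate DHS-like coverage microdata
#'
#' Two-stage sample per survey year: clusters carry a shared random effect on
#' latent wealth (inducing intra-cluster correlation), households add
#' independent noise so latent wealth is standard normal marginally. Binary
#' asset indicators are Bernoulli with probabilities monotone in latent
#' wealth; each service-use outcome is Bernoulli on the logit-linear predictor
#' `a0 + b * (year - year0) + g * wealth + region offset`. Sampling weights
#' are inverse-inclusion-probability-like (log-normal with moderate
#' variation), normalized to sum to the sample size within each year.
#'
#' @param config An `uhc_config`, see [synthetic_config()].
#' @return A tibble with columns `year`, `cluster_id`, `region_id`, `weight`,
#'   `asset_1..asset_K`, `latent_wealth` (generator-only truth, kept for
#'   testing) and one `outcome_<indicator>` column per indicator (0/1/NA).
#' @export
generate_coverage_microdata <- function(config) {
  validate_config(config)
  year0 <- config$survey_years[1]
  withr::with_seed(derive_seed(config$seed, 1L), {
    out <- lapply(config$survey_years, function(yr) {
      nc <- config$n_clusters
      m <- config$households_per_cluster
      n <- nc * m
      cluster_id <- rep(seq_len(nc), each = m)
      region_id <- rep(sample.int(config$n_regions, nc, replace = TRUE), each = m)
      cl_eff <- rep(stats::rnorm(nc, 0, sqrt(config$wealth_icc)), each = m)
      wealth <- cl_eff + stats::rnorm(n, 0, sqrt(1 - config$wealth_icc))
      w_raw <- stats::rlnorm(n, 0, cv_to_sdlog(config$weight_cv))
      weight <- w_raw * n / sum(w_raw)

      cuts <- asset_cuts(config$n_assets)
      load <- asset_loadings(config$n_assets)
      assets <- vapply(seq_len(config$n_assets), function(j) {
        stats::rbinom(n, 1L, inv_logit(cuts[j] + load[j] * wealth))
      }, integer(n))
      colnames(assets) <- paste0("asset_", seq_len(config$n_assets))

      df <- tibble::tibble(year = yr, cluster_id = cluster_id,
                           region_id = region_id, weight = weight)
      df <- dplyr::bind_cols(df, tibble::as_tibble(assets))
      df$latent_wealth <- wealth

      for (nm in names(config$indicator_params)) {
        ip <- config$indicator_params[[nm]]
        col <- paste0("outcome_", nm)
        if (!is.null(ip$start_year) && !is.na(ip$start_year) && yr < ip$start_year) {
          df[[col]] <- NA_integer_
          next
        }
        eta <- ip$a0 + ip$b * (yr - year0) + ip$g * wealth +
          unname(config$region_effects[region_id])
        y <- stats::rbinom(n, 1L, inv_logit(eta))
        if (config$missing_rate > 0) {
          y[stats::runif(n) < config$missing_rate] <- NA_integer_
        }
        df[[col]] <- y
      }
      df
    })
    dplyr::bind_rows(out)
  })
}

#' Generate GLSS-like expenditure microdata
#'
#' Per wave: household size is `1 + Poisson`, per-capita total consumption is
#' log-normal with a slow upward drift across waves, the food share is
#' logit-normal around the wave-specific mean (declining across waves), and
#' out-of-pocket (OOP) health spending is zero-inflated log-normal, capped at
#' non-food expenditure so the OOP share of non-food consumption stays in
#' `[0,1]`. Region offsets act on the OOP location.
#'
#' @param config An `uhc_config`, see [synthetic_config()].
#' @return A tibble with columns `year`, `region_id`, `weight`, `hh_size`,
#'   `exp_total`, `exp_food`, `exp_nonfood`, `oop_health`. `exp_food +
#'   exp_nonfood == exp_total` holds for every row.
#' @export
generate_expenditure_microdata <- function(config) {
  validate_config(config)
  ep <- config$expenditure_params
  year0 <- ep$survey_years[1]
  reg_oop <- rep_len(ep$region_oop_effects, config$n_regions)
  withr::with_seed(derive_seed(config$seed, 2L), {
    out <- lapply(seq_along(ep$survey_years), function(i) {
      yr <- ep$survey_years[i]
      n <- ep$n_households
      region_id <- sample.int(config$n_regions, n, replace = TRUE)
      hh_size <- 1L + stats::rpois(n, ep$mean_hh_size - 1)
      pc_total <- stats::rlnorm(n, ep$log_mean_pc + ep$log_mean_drift * (yr - year0),
                                ep$log_sd_pc)
      exp_total <- pc_total * hh_size
      share <- inv_logit(stats::rnorm(n, logit(ep$mean_food_share[i]),
                                      ep$food_share_sd))
      exp_food <- share * exp_total
      exp_nonfood <- exp_total - exp_food
      any_oop <- stats::rbinom(n, 1L, ep$p_any_oop)
      oop_raw <- stats::rlnorm(n, ep$oop_log_mean[i] + reg_oop[region_id],
                               ep$oop_log_sd)
      oop_health <- pmin(oop_raw, exp_nonfood) * any_oop
      w_raw <- stats::rlnorm(n, 0, cv_to_sdlog(config$weight_cv))
      tibble::tibble(year = yr, region_id = region_id,
                     weight = w_raw * n / sum(w_raw),
                     hh_size = hh_size, exp_total = exp_total,
                     exp_food = exp_food, exp_nonfood = exp_nonfood,
                     oop_health = oop_health)
    })
    dplyr::bind_rows(out)
  })
}

#' Echo the generating (ground-truth) parameters of a configuration
#'
#' Parameter-recovery tests compare estimates against these values.
#' @param config An `uhc_config`.
#' @return List with `indicator_params`, `region_effects`,
#'   `expenditure_params`, exactly as used by the generators.
#' @export
true_parameters <- function(config) {
  validate_config(config)
  list(indicator_params = config$indicator_params,
       region_effects = config$region_effects,
       expenditure_params = config$expenditure_params)
}

#' Read/write a synthetic configuration as YAML
#'
#' @param config An `uhc_config`.
#' @param path File path.
#' @return `write_synthetic_config()` returns `path` invisibly;
#'   `read_synthetic_config()` returns a validated `uhc_config`.
#' @export
write_synthetic_config <- function(config, path) {
  validate_config(config)
  x <- unclass(config)
  x$region_effects <- as.list(x$region_effects)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path) {
  x <- yaml::read_yaml(path)
  re <- unlist(x$region_effects)
  do.call(synthetic_config, c(
    list(survey_years = unlist(x$survey_years),
         n_clusters = x$n_clusters,
         households_per_cluster = x$households_per_cluster,
         n_regions = x$n_regions, n_assets = x$n_assets,
         wealth_icc = x$wealth_icc, weight_cv = x$weight_cv,
         missing_rate = x$missing_rate,
         indicator_params = x$indicator_params,
         region_effects = re,
         expenditure_params = lapply(x$expenditure_params, function(v) {
           if (is.list(v)) unlist(v) else v
         }),
         seed = x$seed)
  ))
}
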