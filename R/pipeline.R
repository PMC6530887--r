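#' Trend-analysis settings for the pipeline
#'
#' @param method `"mcmc"` (default) or `"conjugate"` (exact draws; used by
#'   simulation-heavy tests).
#' @param chains,burn_in,retained MCMC settings (two chains, 5000 burn-in
#'   iterations per chain, 1000 retained draws across chains).
#' @param target Coverage target as a proportion (default 0.80 by 2030).
#' @param target_year Target year (default 2030).
#' @param frp_epsilon Financial-risk-protection threshold: incidence below
#'   this proportion counts as meeting the 100%-protection target.
#' @param coverage_years Years at which coverage projections are reported.
#' @param hardship_years Years at which hardship projections are reported.
#' @param rate_period Two years bounding the annual-rate-of-change period.
#' @return List of settings.
#' @export
uhc_trend_options <- function(method = "mcmc", chains = 2L, burn_in = 5000L,
                              retained = 1000L, target = 0.80,
                              target_year = 2030, frp_epsilon = 0.01,
                              coverage_years = c(1995, 2005, 2015, 2030),
                              hardship_years = c(1995, 2000, 2005, 2010, 2015,
                                                 2020, 2030),
                              rate_period = c(1995, 2030)) {
  list(method = method, chains = chains, burn_in = burn_in,
       retained = retained, target = target, target_year = target_year,
       frp_epsilon = frp_epsilon, coverage_years = coverage_years,
       hardship_years = hardship_years, rate_period = rate_period)
}

fit_one_trend <- function(td, opts, seed, interaction = FALSE) {
  if (opts$method == "mcmc") {
    fit_trend_mcmc(td, chains = opts$chains, burn_in = opts$burn_in,
                   retained = opts$retained, seed = seed,
                   interaction = interaction)
  } else {
    fit_trend_conjugate(td, n_draws = opts$retained, seed = seed,
                        interaction = interaction)
  }
}

# observed series for one indicator -> trend input, boundary-adjusted
series_to_trend <- function(est, group = NULL) {
  d <- est[!is.na(est$p_hat), , drop = FALSE]
  if (nrow(d) == 0L) return(NULL)
  p <- adjust_boundary(d$p_hat, pmax(d$n_eff, 1))
  trend_data(d$year, p, group = group)
}

#' National coverage analysis: trends, projections, target probabilities
#'
#' Runs the full national pipeline on coverage microdata: survey-weighted
#' estimation per indicator-year, logit-linear Bayesian trend per indicator,
#' projected coverage at the report years with 95% credible intervals, the
#' probability of reaching the coverage target by the target year, and the
#' annual rate of change. Composite prevention/treatment indices (pooled by
#' random-effects meta-analysis) and the composite coverage index are
#' appended as extra rows. National financial-hardship trends (catastrophic
#' expenditure, impoverishment, hardship) are computed from the expenditure
#' microdata in the same way.
#'
#' @param config An `uhc_config`; the synthetic microdata are generated from
#'   it. Alternatively pass pre-built microdata via `coverage_data` /
#'   `expenditure_data`.
#' @param opts Trend settings, see [uhc_trend_options()].
#' @param coverage_data,expenditure_data Optional pre-built microdata tables.
#' @param registry Indicator registry.
#' @param che_threshold Catastrophic-spending threshold (default 0.25).
#' @return List with `coverage` (indicator x report-year projections,
#'   Table-1 shape), `hardship` (hardship incidence trajectory, Table-3
#'   shape), and `estimates` (the underlying survey estimates).
#' @export
run_national_analysis <- function(config, opts = uhc_trend_options(),
                                  coverage_data = NULL, expenditure_data = NULL,
                                  registry = default_indicator_registry(),
                                  che_threshold = 0.25) {
  if (is.null(coverage_data)) coverage_data <- generate_coverage_microdata(config)
  if (is.null(expenditure_data)) {
    expenditure_data <- generate_expenditure_microdata(config)
  }
  est <- estimate_all(coverage_data, registry, "national")
  comp <- composite_indices(est, registry)

  rows <- list()
  fit_i <- 0L
  for (ind in unique(est$indicator)) {
    fit_i <- fit_i + 1L
    e <- est[est$indicator == ind, ]
    td <- tryCatch(series_to_trend(e), error = function(err) NULL)
    if (is.null(td)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        indicator = ind, class = e$class[1], year = NA_real_, mean = NA_real_,
        ci_lo = NA_real_, ci_hi = NA_real_, prob_target = NA_real_,
        rate_mean = NA_real_, rate_lo = NA_real_, rate_hi = NA_real_,
        psrf_max = NA_real_, converged = NA, flagged = TRUE)
      next
    }
    fit <- fit_one_trend(td, opts, derive_seed(config$seed, 100L + fit_i))
    pr <- project(fit, opts$coverage_years)
    rate <- annual_rate_of_change(fit, opts$rate_period[1], opts$rate_period[2])
    rows[[length(rows) + 1L]] <- tibble::tibble(
      indicator = ind, class = e$class[1], year = pr$year, mean = pr$mean,
      ci_lo = pr$ci_lo, ci_hi = pr$ci_hi,
      prob_target = prob_target_coverage(fit, opts$target_year, opts$target),
      rate_mean = rate$rate_mean, rate_lo = rate$rate_lo,
      rate_hi = rate$rate_hi, psrf_max = max(psrf(fit)),
      converged = fit$converged, flagged = FALSE)
  }
  for (lab in unique(comp$label)) {
    fit_i <- fit_i + 1L
    cc <- comp[comp$label == lab & !is.na(comp$value), ]
    if (length(unique(cc$year)) < 3L) next
    td <- trend_data(cc$year, adjust_boundary(cc$value / 100, pmax(cc$k, 1) * 100))
    fit <- fit_one_trend(td, opts, derive_seed(config$seed, 100L + fit_i))
    pr <- project(fit, opts$coverage_years)
    rate <- annual_rate_of_change(fit, opts$rate_period[1], opts$rate_period[2])
    rows[[length(rows) + 1L]] <- tibble::tibble(
      indicator = paste0("composite_", lab), class = "composite",
      year = pr$year, mean = pr$mean, ci_lo = pr$ci_lo, ci_hi = pr$ci_hi,
      prob_target = prob_target_coverage(fit, opts$target_year, opts$target),
      rate_mean = rate$rate_mean, rate_lo = rate$rate_lo,
      rate_hi = rate$rate_hi, psrf_max = max(psrf(fit)),
      converged = fit$converged, flagged = FALSE)
  }

  hard <- estimate_hardship_incidence(expenditure_data, threshold = che_threshold)
  hrows <- list()
  for (metric in c("che", "imp", "hardship")) {
    fit_i <- fit_i + 1L
    pcol <- paste0(metric, "_pct")
    td <- trend_data(hard$year, adjust_boundary(hard[[pcol]] / 100, hard$n))
    fit <- fit_one_trend(td, opts, derive_seed(config$seed, 100L + fit_i))
    pr <- project(fit, opts$hardship_years)
    rate <- annual_rate_of_change(fit, opts$rate_period[1], opts$rate_period[2])
    hrows[[length(hrows) + 1L]] <- tibble::tibble(
      metric = metric, year = pr$year, mean = pr$mean, ci_lo = pr$ci_lo,
      ci_hi = pr$ci_hi,
      prob_protection = prob_financial_protection(fit, opts$target_year,
                                                  opts$frp_epsilon),
      rate_mean = rate$rate_mean, rate_lo = rate$rate_lo,
      rate_hi = rate$rate_hi, psrf_max = max(psrf(fit)),
      converged = fit$converged)
  }
  list(coverage = dplyr::bind_rows(rows), hardship = dplyr::bind_rows(hrows),
       estimates = est)
}

#' Equity analysis: wealth-quintile trends and SII/RII
#'
#' Coverage side: per indicator, a wealth-quintile-adjusted logit-linear
#' trend is fitted with and without quintile x year interaction, the model
#' with the smaller DIC is kept, and the slope and relative indices of
#' inequality are computed per report year from the joint posterior draws of
#' the five quintile trajectories. Expenditure side: households are ranked
#' into per-capita-consumption quintiles, catastrophic-expenditure incidence
#' is estimated per quintile-year, and quintile-adjusted trends give the
#' projected poorest/richest incidence and SII/RII per year (Table-4 shape).
#'
#' @inheritParams run_national_analysis
#' @return List with `coverage_sii` (indicator x year SII/RII, Table-2
#'   shape) and `che_inequality` (year x Q1/Q5/RII/SII, Table-4 shape).
#' @export
run_equity_analysis <- function(config, opts = uhc_trend_options(),
                                coverage_data = NULL, expenditure_data = NULL,
                                registry = default_indicator_registry(),
                                che_threshold = 0.25) {
  if (is.null(coverage_data)) coverage_data <- generate_coverage_microdata(config)
  if (is.null(expenditure_data)) {
    expenditure_data <- generate_expenditure_microdata(config)
  }
  coverage_data <- add_wealth_quintiles(coverage_data)
  est <- estimate_all(coverage_data, registry, "quintile")
  ranks <- seq(0.1, 0.9, by = 0.2)   # nominal equal-share quintiles
  shares <- rep(0.2, 5)

  rows <- list()
  fit_i <- 0L
  for (ind in unique(est$indicator)) {
    fit_i <- fit_i + 1L
    e <- est[est$indicator == ind & !is.na(est$p_hat), ]
    if (length(unique(e$year)) < 3L || length(unique(e$group)) < 5L) next
    td <- trend_data(e$year, adjust_boundary(e$p_hat, pmax(e$n_eff, 1)),
                     group = e$group)
    sel <- select_model_by_dic(td, method = opts$method, chains = opts$chains,
                               burn_in = opts$burn_in, retained = opts$retained,
                               seed = derive_seed(config$seed, 300L + fit_i))
    fit <- if (is.null(sel$model)) next else sel$model
    for (yr in opts$coverage_years) {
      D <- vapply(paste0("Q", 1:5), function(g) {
        100 * projection_draws(fit, yr, group = g)[, 1L]
      }, numeric(nrow(fit$draws)))
      ineq <- inequality_from_draws(D, ranks, shares)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(indicator = ind, year = yr,
                       model_choice = if (sel$interaction) "interaction"
                                      else "no_interaction",
                       dic_no_interaction = unname(sel$dic["no_interaction"]),
                       dic_interaction = unname(sel$dic["interaction"])),
        ineq)
    }
  }

  # consumption-based quintiles for the expenditure survey
  ed <- dplyr::bind_rows(lapply(sort(unique(expenditure_data$year)), function(yr) {
    d <- expenditure_data[expenditure_data$year == yr, , drop = FALSE]
    qa <- assign_quintiles(d$exp_total / d$hh_size, d$weight)
    d$quintile <- paste0("Q", qa$quintile)
    d
  }))
  hq <- estimate_hardship_incidence(ed, threshold = che_threshold,
                                    group = "quintile")
  hq <- hq[!is.na(hq$che_pct), ]
  td <- trend_data(hq$year, adjust_boundary(hq$che_pct / 100, hq$n),
                   group = hq$group)
  sel <- select_model_by_dic(td, method = opts$method, chains = opts$chains,
                             burn_in = opts$burn_in, retained = opts$retained,
                             seed = derive_seed(config$seed, 400L))
  che_rows <- list()
  if (!is.null(sel$model)) {
    fit <- sel$model
    for (yr in opts$hardship_years) {
      D <- vapply(paste0("Q", 1:5), function(g) {
        100 * projection_draws(fit, yr, group = g)[, 1L]
      }, numeric(nrow(fit$draws)))
      ineq <- inequality_from_draws(D, ranks, shares)
      q1 <- stats::quantile(D[, 1L], c(0.025, 0.975), names = FALSE)
      q5 <- stats::quantile(D[, 5L], c(0.025, 0.975), names = FALSE)
      che_rows[[length(che_rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(year = yr,
                       q1_mean = mean(D[, 1L]), q1_lo = q1[1], q1_hi = q1[2],
                       q5_mean = mean(D[, 5L]), q5_lo = q5[1], q5_hi = q5[2]),
        ineq)
    }
  }
  list(coverage_sii = dplyr::bind_rows(rows),
       che_inequality = dplyr::bind_rows(che_rows))
}

#' Subnational analysis: regional hardship and composite-coverage trends
#'
#' Per region: a logit-linear trend of catastrophic-expenditure incidence
#' with projections at the hardship report years and the probability of
#' achieving financial risk protection (Table-5 shape); and random-effects
#' composite prevention/treatment indices with projections and the
#' probability of reaching the coverage target. Regions observed in fewer
#' than two survey waves are excluded with a warning.
#'
#' @inheritParams run_national_analysis
#' @return List with `che_by_region` and `composites_by_region` tibbles.
#' @export
run_subnational_analysis <- function(config, opts = uhc_trend_options(),
                                     coverage_data = NULL,
                                     expenditure_data = NULL,
                                     registry = default_indicator_registry(),
                                     che_threshold = 0.25) {
  if (is.null(coverage_data)) coverage_data <- generate_coverage_microdata(config)
  if (is.null(expenditure_data)) {
    expenditure_data <- generate_expenditure_microdata(config)
  }
  region_names <- names(config$region_effects)
  reg_label <- function(id) {
    id <- as.integer(id)
    if (!is.null(region_names)) region_names[id] else as.character(id)
  }

  hr <- estimate_hardship_incidence(expenditure_data, threshold = che_threshold,
                                    group = "region")
  rows <- list()
  fit_i <- 0L
  for (g in sort(unique(hr$group))) {
    fit_i <- fit_i + 1L
    e <- hr[hr$group == g & !is.na(hr$che_pct), ]
    if (length(unique(e$year)) < 2L) {
      warning("region ", g, " has fewer than 2 survey waves; excluded",
              call. = FALSE)
      next
    }
    if (length(unique(e$year)) < 3L) next
    td <- trend_data(e$year, adjust_boundary(e$che_pct / 100, e$n))
    fit <- fit_one_trend(td, opts, derive_seed(config$seed, 500L + fit_i))
    pr <- project(fit, opts$hardship_years)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      region = reg_label(g), year = pr$year, che_mean = pr$mean,
      che_lo = pr$ci_lo, che_hi = pr$ci_hi,
      prob_protection = prob_financial_protection(fit, opts$target_year,
                                                  opts$frp_epsilon),
      psrf_max = max(psrf(fit)), converged = fit$converged)
  }

  est <- estimate_all(coverage_data, registry, "region")
  comp <- composite_indices(est, registry)
  crow <- list()
  for (lab in c("prevention", "treatment")) {
    for (g in sort(unique(comp$group))) {
      fit_i <- fit_i + 1L
      cc <- comp[comp$label == lab & comp$group == g & !is.na(comp$value), ]
      if (length(unique(cc$year)) < 3L) next
      td <- trend_data(cc$year, adjust_boundary(cc$value / 100, 100 * pmax(cc$k, 1)))
      fit <- fit_one_trend(td, opts, derive_seed(config$seed, 500L + fit_i))
      pr <- project(fit, opts$coverage_years)
      crow[[length(crow) + 1L]] <- tibble::tibble(
        label = lab, region = reg_label(g), year = pr$year, mean = pr$mean,
        ci_lo = pr$ci_lo, ci_hi = pr$ci_hi,
        prob_target = prob_target_coverage(fit, opts$target_year, opts$target),
        psrf_max = max(psrf(fit)), converged = fit$converged)
    }
  }
  list(che_by_region = dplyr::bind_rows(rows),
       composites_by_region = dplyr::bind_rows(crow))
}

#' Write report tables and a run manifest
#'
#' One CSV per report table plus `manifest.json` recording the seed, a hash
#' of the configuration, package and R versions, and the runtime.
#'
#' @param results Named list of data frames (as returned by the `run_*`
#'   functions, flattened).
#' @param outdir Output directory (created if needed).
#' @param config The `uhc_config` used.
#' @param runtime_sec Optional elapsed seconds to record.
#' @return Invisibly, the paths written.
#' @export
write_report_tables <- function(results, outdir, config, runtime_sec = NA) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  probe <- file.path(outdir, ".write_test")
  ok <- tryCatch({ file.create(probe) }, warning = function(w) FALSE)
  if (!isTRUE(ok)) stop("output directory not writable: ", outdir, call. = FALSE)
  unlink(probe)

  paths <- character(0)
  for (nm in names(results)) {
    if (!is.data.frame(results[[nm]])) next
    path <- file.path(outdir, paste0(nm, ".csv"))
    utils::write.csv(results[[nm]], path, row.names = FALSE)
    paths <- c(paths, path)
  }
  manifest <- list(
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    package_version = as.character(utils::packageVersion("uhcmonitor")),
    r_version = as.character(getRversion()),
    created = format(Sys.time(), tz = "UTC"),
    runtime_sec = runtime_sec,
    tables = basename(paths)
  )
  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, mpath))
}

#' Run the full pipeline on one configuration
#'
#' Generation, wealth, coverage, hardship, inequality, and trend analysis in
#' sequence, emitting the five report-table shapes (national coverage,
#' coverage inequality, national hardship, hardship inequality, subnational
#' hardship) plus regional composites, all written as CSV with a JSON
#' manifest. Deterministic given the config (which carries the seed).
#'
#' @param config An `uhc_config`.
#' @param outdir Output directory; `NULL` skips writing.
#' @param opts Trend settings, see [uhc_trend_options()].
#' @return Named list of report tables (invisibly if written).
#' @export
run_uhc_pipeline <- function(config, outdir = NULL,
                             opts = uhc_trend_options()) {
  t0 <- Sys.time()
  cov <- generate_coverage_microdata(config)
  exp <- generate_expenditure_microdata(config)
  nat <- run_national_analysis(config, opts, cov, exp)
  eq <- run_equity_analysis(config, opts, cov, exp)
  sub <- run_subnational_analysis(config, opts, cov, exp)
  tables <- list(
    table1_national_coverage = nat$coverage,
    table2_coverage_sii = eq$coverage_sii,
    table3_hardship_national = nat$hardship,
    table4_che_inequality = eq$che_inequality,
    table5_subnational_che = sub$che_by_region,
    subnational_composites = sub$composites_by_region
  )
  if (!is.null(outdir)) {
    write_report_tables(tables, outdir, config,
                        as.numeric(difftime(Sys.time(), t0, units = "secs")))
    return(invisible(tables))
  }
  tables
}

#' Demo scenario configuration
#'
#' A scaled-down synthetic scenario (40 clusters of 12 households per
#' coverage wave, 1200 households per expenditure wave) that exercises the
#' entire pipeline in well under two minutes.
#'
#' @param seed Integer seed.
#' @return An `uhc_config`.
#' @export
demo_config <- function(seed = 20301L) {
  ep <- default_expenditure_params()
  ep$n_households <- 1200
  synthetic_config(n_clusters = 40, households_per_cluster = 12,
                   expenditure_params = ep, seed = seed)
}

#' Run the end-to-end demo
#'
#' Full pipeline on the demo scenario; living documentation of every stage.
#'
#' @param outdir Output directory (default a temporary directory).
#' @param seed Integer seed.
#' @return Named list of report tables.
#' @export
run_demo <- function(outdir = tempfile("uhc_demo_"), seed = 20301L) {
  run_uhc_pipeline(demo_config(seed), outdir)
}
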