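# Shared fixtures and independent oracles, all built in code.

tiny_config <- function(seed = 42L, ...) {
  ep <- default_expenditure_params()
  ep$n_households <- 400
  synthetic_config(n_clusters = 20, households_per_cluster = 10,
                   expenditure_params = ep, seed = seed, ...)
}

# one-indicator configuration with flat/no-gradient defaults, overridable
flat_config <- function(a0 = 0, b = 0, g = 0, seed = 7L, n_clusters = 20,
                        households_per_cluster = 10,
                        survey_years = c(2000, 2005, 2010)) {
  synthetic_config(
    survey_years = survey_years, n_clusters = n_clusters,
    households_per_cluster = households_per_cluster,
    n_regions = 4, n_assets = 6,
    indicator_params = list(ind = list(a0 = a0, b = b, g = g)),
    region_effects = rep(0, 4), seed = seed)
}

# brute-force weighted least squares: scalar accumulation, no shared code
# with slope_and_relative_index()
wls_oracle <- function(v, r, s) {
  sw <- sum(s)
  mx <- 0; my <- 0
  for (i in seq_along(v)) {
    mx <- mx + s[i] * r[i] / sw
    my <- my + s[i] * v[i] / sw
  }
  num <- 0; den <- 0
  for (i in seq_along(v)) {
    num <- num + s[i] * (r[i] - mx) * (v[i] - my)
    den <- den + s[i] * (r[i] - mx)^2
  }
  b <- num / den
  a <- my - b * mx
  list(sii = b, f0 = a, f1 = a + b)
}

# row-by-row hardship oracle: plain ifs, independent of hardship_flags()
hardship_oracle_row <- function(total, nonfood, oop, hh_size, pl, threshold) {
  share <- if (nonfood > 0) oop / nonfood else if (oop > 0) 1 else 0
  che <- if (share > threshold) 1L else 0L
  pre_poor <- if (total / hh_size < pl) 1L else 0L
  imp <- if (pre_poor == 0L && (total - oop) / hh_size < pl) 1L else 0L
  hard <- if (che == 1L || imp == 1L) 1L else 0L
  c(che = che, pre_poor = pre_poor, impoverished = imp, hardship = hard)
}

# 20-household toy expenditure table with hand-evaluated flags (poverty
# line fixed at 50, catastrophic threshold 0.25, per-capita comparisons)
toy_expenditure_table <- function() {
  tab <- tibble::tribble(
    ~exp_total, ~exp_nonfood, ~oop_health, ~hh_size, ~che, ~imp,
    200,   100,   0,  1, 0L, 0L,   # no OOP
    200,   100,  30,  1, 1L, 0L,   # share .30 > .25
    200,   100,  25,  1, 0L, 0L,   # share exactly .25: not catastrophic
    60,     30,  15,  1, 1L, 1L,   # share .50; 60 >= 50 but 45 < 50
    55,     20,   4,  1, 0L, 0L,   # share .20; 51 >= 50
    55,     20,   6,  1, 1L, 1L,   # share .30; 49 < 50
    40,     10,   2,  1, 0L, 0L,   # already poor (40 < 50): never impoverished
    45,     20,  10,  1, 1L, 0L,   # already poor but catastrophic
    100,    40,  12,  1, 1L, 0L,   # share .30
    100,    40,  10,  1, 0L, 0L,   # share .25 boundary
    52,     26,   3,  1, 0L, 1L,   # share .115; 49 < 50 and 52 >= 50
    52,     26,  13,  1, 1L, 1L,   # share .50; 39 < 50
    500,   300, 100,  1, 1L, 0L,   # share .33
    500,   300,  60,  1, 0L, 0L,   # share .20
    49.9,   25,   0,  1, 0L, 0L,   # poor, no OOP
    50,     25,   0,  1, 0L, 0L,   # exactly at the line, no OOP
    80,     40,  40,  1, 1L, 1L,   # share 1; 40 < 50
    300,   100,  26,  1, 1L, 0L,   # share .26
    70,     35,  21,  1, 1L, 1L,   # share .60; 49 < 50
    120,    60,  24,  2, 1L, 1L    # per-capita 60 -> 48 after OOP; share .40
  )
  tab$year <- 2000
  tab$region_id <- 1L
  tab$weight <- 1
  tab$exp_food <- tab$exp_total - tab$exp_nonfood
  tab$hardship <- as.integer(tab$che == 1L | tab$imp == 1L)
  tab
}

# uhc_draws object with fixed parameter values (delta "posterior"), used to
# test deterministic summaries of projections and rates
delta_draws <- function(alpha, beta, t0, sigma2 = 1e-8, n = 2L) {
  data <- trend_data(t0 + c(0, 1, 2), inv_logit(alpha + beta * c(0, 1, 2)))
  des <- list(X = cbind(alpha = 1, beta = c(0, 1, 2)), y = data$y, t0 = t0,
              groups = NULL, interaction = FALSE)
  draws <- tibble::tibble(chain = 1L, iter = seq_len(n),
                          alpha = rep(alpha, n), beta = rep(beta, n),
                          sigma2 = rep(sigma2, n))
  structure(list(draws = draws, X = des$X, y = des$y, t0 = t0, groups = NULL,
                 interaction = FALSE, method = "delta", converged = TRUE,
                 psrf = c(alpha = 1, beta = 1, sigma2 = 1), n_iter = n),
            class = "uhc_draws")
}
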