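test_that("generation is deterministic under a fixed seed and config", {
  cfg <- tiny_config(seed = 11L)
  expect_identical(generate_coverage_microdata(cfg),
                   generate_coverage_microdata(cfg))
  expect_identical(generate_expenditure_microdata(cfg),
                   generate_expenditure_microdata(cfg))
  cfg2 <- tiny_config(seed = 12L)
  expect_false(identical(generate_coverage_microdata(cfg),
                         generate_coverage_microdata(cfg2)))
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(survey_years = c(2000, 2000, 2005)),
               "strictly increasing")
  expect_error(synthetic_config(n_clusters = 0), "positive")
  ep <- default_expenditure_params()
  ep$mean_food_share <- c(0.6, 0.6, 0.6, 1.2)
  expect_error(synthetic_config(expenditure_params = ep), "food_share")
})

test_that("a null model yields pooled coverage near one half", {
  cfg <- flat_config(a0 = 0, b = 0, g = 0, n_clusters = 50,
                     households_per_cluster = 20)
  md <- generate_coverage_microdata(cfg)
  p <- sum(md$weight * md$outcome_ind) / sum(md$weight)
  n <- nrow(md)
  expect_lt(abs(p - 0.5), 3.5 * sqrt(0.25 / n))
})

test_that("a positive year slope raises coverage in the last wave", {
  hits <- 0L
  for (s in 1:100) {
    cfg <- flat_config(a0 = -0.5, b = 0.1, g = 0, seed = 1000L + s,
                       n_clusters = 10, households_per_cluster = 10)
    md <- generate_coverage_microdata(cfg)
    first <- md[md$year == 2000, ]
    last <- md[md$year == 2010, ]
    p1 <- sum(first$weight * first$outcome_ind) / sum(first$weight)
    p2 <- sum(last$weight * last$outcome_ind) / sum(last$weight)
    if (p2 > p1) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("weighted coverage converges to the generating probability", {
  cfg <- flat_config(a0 = -0.4, b = 0, g = 0, n_clusters = 100,
                     households_per_cluster = 100,
                     survey_years = c(2000, 2001, 2002))
  md <- generate_coverage_microdata(cfg)
  d <- md[md$year == 2000, ]
  p_true <- inv_logit(-0.4)
  p_hat <- sum(d$weight * d$outcome_ind) / sum(d$weight)
  se <- sqrt(p_true * (1 - p_true) * sum(d$weight^2) / sum(d$weight)^2)
  expect_lt(abs(p_hat - p_true), 2 * se)
})

test_that("coverage microdata satisfies its structural invariants", {
  cfg <- tiny_config()
  md <- generate_coverage_microdata(cfg)
  expect_true(all(md$weight > 0))
  for (yr in cfg$survey_years) {
    d <- md[md$year == yr, ]
    expect_equal(sum(d$weight), nrow(d))
    expect_true(all(table(d$cluster_id) >= 1))
    # moderate weight variation, no extreme-weight pathologies
    expect_lt(stats::sd(d$weight) / mean(d$weight), 0.3)
  }
  outc <- md[, grep("^outcome_", names(md))]
  expect_true(all(as.matrix(outc) %in% c(0L, 1L, NA)))
  # indicators that entered the survey late are missing before their start
  expect_true(all(is.na(md$outcome_itn_children[md$year < 2003])))
  expect_false(anyNA(md$outcome_itn_children[md$year >= 2003]))
})

test_that("expenditure microdata satisfies the accounting identities", {
  md <- generate_expenditure_microdata(tiny_config())
  expect_equal(md$exp_food + md$exp_nonfood, md$exp_total, tolerance = 1e-12)
  expect_true(all(md$oop_health <= md$exp_nonfood + 1e-9))
  expect_true(all(md$oop_health >= 0))
  expect_true(all(md$hh_size >= 1 & md$hh_size == round(md$hh_size)))
  expect_true(all(md$exp_total > 0))
})

test_that("no out-of-pocket spending means no catastrophic expenditure", {
  cfg <- tiny_config()
  cfg$expenditure_params$p_any_oop <- 0
  md <- generate_expenditure_microdata(cfg)
  expect_true(all(md$oop_health == 0))
  inc <- estimate_hardship_incidence(md)
  expect_true(all(inc$che_pct == 0))
})

test_that("generated food share matches its target on average", {
  ep <- default_expenditure_params()
  ep$n_households <- 2500
  ep$mean_food_share <- rep(0.6, 4)
  ep$food_share_sd <- 0.3
  cfg <- synthetic_config(expenditure_params = ep, seed = 5L)
  md <- generate_expenditure_microdata(cfg)
  fs <- sum(md$weight * md$exp_food / md$exp_total) / sum(md$weight)
  expect_gt(fs, 0.59)
  expect_lt(fs, 0.61)
})

test_that("true parameters echo the configuration and survive a round trip", {
  cfg <- tiny_config()
  cfg$indicator_params$bcg$b <- 0.05
  tp <- true_parameters(cfg)
  expect_identical(tp$indicator_params$bcg$b, 0.05)

  path <- withr::local_tempfile(fileext = ".yaml")
  write_synthetic_config(cfg, path)
  cfg2 <- read_synthetic_config(path)
  expect_equal(true_parameters(cfg2), tp, tolerance = 1e-12)

  cfg3 <- cfg
  cfg3$indicator_params$bcg$b <- 0.06
  expect_false(isTRUE(all.equal(true_parameters(cfg3), tp)))
})
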