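test_that("out-of-pocket shares follow the accounting rules", {
  expect_equal(compute_oop_share(12, 40), 0.3)
  expect_equal(compute_oop_share(0, 40), 0)
  expect_equal(compute_oop_share(40, 40), 1)
  expect_equal(compute_oop_share(0, 0), 0)
  expect_warning(s <- compute_oop_share(5, 0), "zero non-food")
  expect_equal(s, 1)
})

test_that("the catastrophic flag is strict at the threshold", {
  expect_identical(flag_catastrophic(0.30), 1L)
  expect_identical(flag_catastrophic(0.25), 0L)
  expect_identical(flag_catastrophic(0.251), 1L)
  expect_identical(flag_catastrophic(0, threshold = 0), 0L)
})

pl_microdata <- function(total, food, hh = rep(1, length(total)),
                         w = rep(1, length(total)), year = 2000) {
  tibble::tibble(year = year, region_id = 1L, weight = w, hh_size = hh,
                 exp_total = total, exp_food = food,
                 exp_nonfood = total - food, oop_health = 0)
}

test_that("poverty line equals the band households' mean food spending", {
  # shares .3/.5/.7: the 45th-55th percentile band selects the middle one
  md <- pl_microdata(c(100, 100, 100), c(30, 50, 70))
  pl <- estimate_poverty_line(md, 2000)
  expect_equal(pl$value, 50)
  expect_equal(pl$n_band, 1L)
})

test_that("poverty line is invariant to weight and currency rescaling", {
  withr::with_seed(31, {
    total <- stats::rlnorm(100, 5, 0.5)
    share <- stats::runif(100, 0.2, 0.8)
    w <- stats::runif(100, 0.5, 3)
  })
  md <- pl_microdata(total, share * total, w = w)
  pl <- estimate_poverty_line(md, 2000)

  md_w <- md; md_w$weight <- 2 * md_w$weight
  expect_equal(estimate_poverty_line(md_w, 2000)$value, pl$value)

  md_c <- md
  for (v in c("exp_total", "exp_food", "exp_nonfood")) md_c[[v]] <- 100 * md_c[[v]]
  expect_equal(estimate_poverty_line(md_c, 2000)$value, 100 * pl$value)

  md_same <- pl_microdata(rep(80, 10), rep(40, 10))
  expect_equal(estimate_poverty_line(md_same, 2000)$value, 40)
})

test_that("impoverishment requires crossing the line because of OOP", {
  md <- tibble::tibble(year = 2000, region_id = 1L, weight = 1,
                       hh_size = 1,
                       exp_total = c(60, 40, 70),
                       exp_food = c(20, 15, 30),
                       exp_nonfood = c(40, 25, 40),
                       oop_health = c(15, 2, 0))
  fl <- hardship_flags(md, poverty_lines = list(`2000` = 50))
  # 60 -> 45 crosses; 40 was already poor; zero OOP cannot impoverish
  expect_identical(fl$impoverished, c(1L, 0L, 0L))
  expect_identical(fl$pre_poor, c(0L, 1L, 0L))
})

test_that("hardship is the union of catastrophe and impoverishment", {
  base <- tibble::tibble(year = 2000, region_id = 1L, weight = 1, hh_size = 1,
                         exp_total = c(200, 100, 60, 200, 200),
                         exp_food = c(100, 60, 30, 100, 100),
                         exp_nonfood = c(100, 40, 30, 100, 100),
                         oop_health = c(0, 15, 12, 0, 0))
  # household 2: share .375 catastrophic, stays above the line (85 >= 50)
  # household 3: share .40 catastrophic AND 60 -> 48 impoverished
  inc <- estimate_hardship_incidence(base, poverty_lines = list(`2000` = 50))
  expect_equal(inc$che_pct, 40)
  expect_equal(inc$imp_pct, 20)
  expect_equal(inc$hardship_pct, 40)  # union, not sum

  # disjoint case: household 3 no longer spends, household 4 becomes
  # impoverished without catastrophe (share 12/50 = .24, 60 -> 48 < 50)
  base$oop_health <- c(0, 15, 0, 12, 0)
  base$exp_total[4] <- 60; base$exp_food[4] <- 10; base$exp_nonfood[4] <- 50
  inc2 <- estimate_hardship_incidence(base, poverty_lines = list(`2000` = 50))
  expect_equal(inc2$che_pct, 20)
  expect_equal(inc2$imp_pct, 20)
  expect_equal(inc2$hardship_pct, 40)
})

test_that("CHE incidence is non-increasing in the threshold", {
  md <- generate_expenditure_microdata(tiny_config())
  incs <- vapply(c(0.10, 0.25, 0.40), function(th) {
    mean(estimate_hardship_incidence(md, threshold = th)$che_pct)
  }, numeric(1))
  expect_true(all(diff(incs) <= 0))
})

test_that("incidences are invariant to currency rescaling", {
  md <- generate_expenditure_microdata(tiny_config())
  md2 <- md
  for (v in c("exp_total", "exp_food", "exp_nonfood", "oop_health")) {
    md2[[v]] <- 1000 * md2[[v]]
  }
  a <- estimate_hardship_incidence(md)
  b <- estimate_hardship_incidence(md2)
  expect_equal(a$che_pct, b$che_pct, tolerance = 1e-12)
  expect_equal(a$imp_pct, b$imp_pct, tolerance = 1e-12)
  expect_equal(a$hardship_pct, b$hardship_pct, tolerance = 1e-12)
})

test_that("flags agree with a brute-force row-by-row oracle", {
  for (s in c(101L, 202L, 303L)) {
    cfg <- tiny_config(seed = s)
    cfg$expenditure_params$n_households <- 20
    md <- generate_expenditure_microdata(cfg)
    md <- md[md$year == md$year[1], ]
    pl <- estimate_poverty_line(md, md$year[1])
    fl <- hardship_flags(md, poverty_lines = stats::setNames(list(pl),
                                                             md$year[1]))
    for (i in seq_len(nrow(md))) {
      o <- hardship_oracle_row(md$exp_total[i], md$exp_nonfood[i],
                               md$oop_health[i], md$hh_size[i], pl$value, 0.25)
      expect_identical(fl$che[i], o[["che"]])
      expect_identical(fl$pre_poor[i], o[["pre_poor"]])
      expect_identical(fl$impoverished[i], o[["impoverished"]])
      expect_identical(fl$hardship[i], o[["hardship"]])
    }
  }
})

test_that("union bounds hold on every synthetic run and group", {
  md <- generate_expenditure_microdata(tiny_config(seed = 55L))
  inc <- estimate_hardship_incidence(md, group = "region")
  inc <- inc[!is.na(inc$che_pct), ]
  expect_true(all(inc$hardship_pct >= pmax(inc$che_pct, inc$imp_pct) - 1e-9))
  expect_true(all(inc$hardship_pct <= inc$che_pct + inc$imp_pct + 1e-9))
})
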