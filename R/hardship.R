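#' Out-of-pocket share of non-food consumption
#'
#' The catastrophic-payment indicator is built on the ratio of a household's
#' out-of-pocket (OOP) health payments to its non-food consumption
#' expenditure. A household with no non-food consumption but positive OOP
#' spending is assigned the maximal share 1 (with a warning); zero OOP with
#' zero non-food gives share 0.
#'
#' @param oop OOP health payments (>= 0).
#' @param nonfood Non-food consumption expenditure (>= 0).
#' @return Numeric vector of shares in `[0, 1]` (OOP is capped at non-food
#'   spending by the accounting identity).
#' @export
compute_oop_share <- function(oop, nonfood) {
  stopifnot(length(oop) == length(nonfood), all(oop >= 0), all(nonfood >= 0))
  share <- ifelse(nonfood > 0, oop / nonfood, ifelse(oop > 0, 1, 0))
  if (any(nonfood == 0 & oop > 0)) {
    warning("household(s) with zero non-food expenditure but positive OOP; ",
            "share set to 1", call. = FALSE)
  }
  share
}

#' Flag catastrophic health expenditure
#'
#' A household's spending is catastrophic when its OOP share of non-food
#' consumption strictly exceeds the threshold (default 25%).
#'
#' @param share OOP share in `[0, 1]`.
#' @param threshold Catastrophic threshold (default 0.25).
#' @return Integer 0/1 vector.
#' @export
flag_catastrophic <- function(share, threshold = 0.25) {
  stopifnot(all(share >= 0), all(share <= 1))
  as.integer(share > threshold)
}

#' Food-share-based poverty line
#'
#' The poverty line is the weighted mean per-capita food expenditure of the
#' households whose food share of total consumption lies within the weighted
#' 45th-55th percentile band (a food-based subsistence line). Percentiles use
#' the lower-inclusive inverse-CDF definition of [weighted_quantile()]; an
#' empty band (possible under extreme weights) is widened symmetrically by
#' one percentile at a time until nonempty, with a message.
#'
#' @param microdata Expenditure microdata (see
#'   [generate_expenditure_microdata()]).
#' @param year Survey year.
#' @return List of class `uhc_poverty_line`: `value` (currency per capita),
#'   `band` (food-share bounds used), `n_band` (households in the band),
#'   `year`.
#' @export
estimate_poverty_line <- function(microdata, year) {
  d <- microdata[microdata$year == year, , drop = FALSE]
  if (nrow(d) < 3L) stop("need at least 3 households in year ", year, call. = FALSE)
  share <- d$exp_food / d$exp_total
  lo_p <- 0.45; hi_p <- 0.55
  repeat {
    band <- weighted_quantile(share, d$weight, c(lo_p, hi_p))
    sel <- share >= band[1] - 1e-12 & share <= band[2] + 1e-12
    if (any(sel)) break
    lo_p <- max(0, lo_p - 0.01); hi_p <- min(1, hi_p + 0.01)
    message("poverty-line band empty; widened to [", lo_p, ", ", hi_p, "]")
  }
  pc_food <- d$exp_food / d$hh_size
  structure(list(value = wmean(pc_food[sel], d$weight[sel]),
                 band = band, n_band = sum(sel), year = year),
            class = "uhc_poverty_line")
}

#' Household-level financial-hardship flags
#'
#' Computes, per household: the OOP share of non-food consumption; the
#' catastrophic flag (share strictly above `threshold`); pre-payment poverty
#' (per-capita total expenditure below the poverty line); impoverishment
#' (a *non-poor* household whose per-capita expenditure net of OOP falls
#' below the poverty line); and hardship, the union of catastrophe and
#' impoverishment.
#'
#' @param microdata Expenditure microdata (single or multiple years).
#' @param poverty_lines Named list/vector of poverty-line values keyed by
#'   year (or `uhc_poverty_line` objects); by default estimated per year via
#'   [estimate_poverty_line()].
#' @param threshold Catastrophic threshold (default 0.25).
#' @return The microdata with added columns `oop_share`, `che`, `pre_poor`,
#'   `impoverished`, `hardship`, `poverty_line`.
#' @export
hardship_flags <- function(microdata, poverty_lines = NULL, threshold = 0.25) {
  years <- sort(unique(microdata$year))
  if (is.null(poverty_lines)) {
    poverty_lines <- lapply(stats::setNames(years, years),
                            function(yr) estimate_poverty_line(microdata, yr))
  }
  pl_val <- vapply(years, function(yr) {
    pl <- poverty_lines[[as.character(yr)]]
    if (inherits(pl, "uhc_poverty_line")) pl$value else as.numeric(pl)
  }, numeric(1))
  names(pl_val) <- years

  d <- microdata
  d$poverty_line <- unname(pl_val[as.character(d$year)])
  d$oop_share <- compute_oop_share(d$oop_health, d$exp_nonfood)
  d$che <- flag_catastrophic(d$oop_share, threshold)
  pc_total <- d$exp_total / d$hh_size
  pc_net <- (d$exp_total - d$oop_health) / d$hh_size
  d$pre_poor <- as.integer(pc_total < d$poverty_line)
  d$impoverished <- as.integer(d$pre_poor == 0L & pc_net < d$poverty_line)
  d$hardship <- as.integer(d$che == 1L | d$impoverished == 1L)
  d
}

#' Weighted incidence of financial hardship
#'
#' Weighted proportions of catastrophic health expenditure, impoverishment,
#' and their union (financial hardship), per year and optional grouping,
#' with linearized 95% confidence intervals (households treated as
#' independent sampling units in the consumption survey).
#'
#' @param microdata Expenditure microdata.
#' @param poverty_lines Optional poverty lines per year, see
#'   [hardship_flags()].
#' @param threshold Catastrophic threshold (default 0.25).
#' @param group `"national"` (default) or `"region"`, or the name of any
#'   column of `microdata` to group by (e.g. a quintile column added by the
#'   caller).
#' @return Tibble: `year`, `group_type`, `group`, incidence percents
#'   `che_pct`, `imp_pct`, `hardship_pct` with `_lo`/`_hi` 95% bounds,
#'   `poverty_line`, `n`.
#' @export
estimate_hardship_incidence <- function(microdata, poverty_lines = NULL,
                                        threshold = 0.25, group = "national") {
  d <- hardship_flags(microdata, poverty_lines, threshold)
  gcol <- switch(group, national = NULL, region = "region_id", group)
  if (!is.null(gcol) && !gcol %in% names(d)) {
    stop("grouping column not found: ", gcol, call. = FALSE)
  }
  cells <- if (is.null(gcol)) {
    tibble::tibble(year = sort(unique(d$year)), g = "national")
  } else {
    tidyr::expand_grid(year = sort(unique(d$year)),
                       g = sort(unique(d[[gcol]])))
  }
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    dd <- d[d$year == cells$year[i], , drop = FALSE]
    if (!is.null(gcol)) dd <- dd[dd[[gcol]] == cells$g[i], , drop = FALSE]
    if (nrow(dd) == 0L) {
      return(tibble::tibble(year = cells$year[i], group_type = group,
                            group = as.character(cells$g[i]),
                            che_pct = NA_real_, che_lo = NA_real_, che_hi = NA_real_,
                            imp_pct = NA_real_, imp_lo = NA_real_, imp_hi = NA_real_,
                            hardship_pct = NA_real_, hardship_lo = NA_real_,
                            hardship_hi = NA_real_,
                            poverty_line = NA_real_, n = 0L))
    }
    one <- function(y) {
      r <- svy_prop(y, dd$weight, cluster = seq_along(y))
      c(100 * r$p, 100 * r$lo, 100 * r$hi)
    }
    che <- one(dd$che); imp <- one(dd$impoverished); hs <- one(dd$hardship)
    tibble::tibble(year = cells$year[i], group_type = group,
                   group = as.character(cells$g[i]),
                   che_pct = che[1], che_lo = che[2], che_hi = che[3],
                   imp_pct = imp[1], imp_lo = imp[2], imp_hi = imp[3],
                   hardship_pct = hs[1], hardship_lo = hs[2], hardship_hi = hs[3],
                   poverty_line = dd$poverty_line[1], n = nrow(dd))
  })
  dplyr::bind_rows(rows)
}
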