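# Season-level aggregation and the study's statistics: per-season summary
# tables, multi-season pooling, event descriptives, Pearson correlation,
# and the mixed-model ambient-temperature contrast.

#' Summarize one season of drop events
#'
#' Builds the season-table row: nests observed (continuously occupied at
#' least `min_nights` consecutive nights), observations (sum of occupied
#' nights over those nests), nests and nights with drops, and the two
#' percentages. Percentages round half-up: nights to 1 decimal, nests to
#' the nearest integer (the season table's printed precision).
#'
#' @param events Drop events (deduplicated to one per nest-night).
#' @param occupancy Occupancy records from [infer_occupancy()].
#' @param year Season label (integer year).
#' @param min_nights Consecutive-occupancy requirement, nights.
#' @return One-row tibble (`SeasonSummary`): `year`, `n_nests_observed`,
#'   `n_observations`, `n_nests_with_drops`, `n_nights_with_drops`,
#'   `pct_nests_with_drop`, `pct_nights_with_drops`.
#' @export
summarize_season <- function(events, occupancy, year, min_nights = 30L) {
  sel <- select_monitored_nests(occupancy, min_nights = min_nights)
  kept <- sel$nest_id[sel$selected]
  n_nests <- length(kept)
  n_obs <- sum(sel$n_occupied_nights[sel$selected])
  occ_keys <- with(occupancy[occupancy$nest_id %in% kept &
                               occupancy$occupied %in% TRUE, ],
                   paste(nest_id, night_date))
  ev <- events[events$nest_id %in% kept &
                 paste(events$nest_id, events$night_date) %in% occ_keys, ]
  counts_to_summary(
    year = year, n_nests_observed = n_nests, n_observations = n_obs,
    n_nests_with_drops = dplyr::n_distinct(ev$nest_id),
    n_nights_with_drops = nrow(dplyr::distinct(ev, .data$nest_id, .data$night_date))
  )
}

#' Build season summaries from printed per-season counts
#'
#' Computes the two drop percentages (and their declared rounding) from
#' count columns, e.g. from [swift_colony_counts()].
#'
#' @param counts Tibble with `year`, `n_nests_observed`, `n_observations`,
#'   `n_nests_with_drops`, `n_nights_with_drops`.
#' @return Season-summary tibble, one row per input row.
#' @export
#' @examples
#' season_summaries(swift_colony_counts())
season_summaries <- function(counts) {
  purrr::pmap(counts[, c("year", "n_nests_observed", "n_observations",
                         "n_nests_with_drops", "n_nights_with_drops")],
              counts_to_summary) |>
    dplyr::bind_rows()
}

counts_to_summary <- function(year, n_nests_observed, n_observations,
                              n_nests_with_drops, n_nights_with_drops) {
  if (n_nights_with_drops > n_observations ||
      n_nests_with_drops > n_nests_observed) {
    stop_invalid("Drop counts cannot exceed observation counts.")
  }
  tibble::tibble(
    year = year,
    n_nests_observed = n_nests_observed,
    n_observations = n_observations,
    n_nests_with_drops = n_nests_with_drops,
    n_nights_with_drops = n_nights_with_drops,
    pct_nests_with_drop = if (n_nests_observed > 0)
      round_half_up(100 * n_nests_with_drops / n_nests_observed, 0) else NA_real_,
    pct_nights_with_drops = if (n_observations > 0)
      round_half_up(100 * n_nights_with_drops / n_observations, 1) else NA_real_
  )
}

#' Pool several season summaries
#'
#' Totals are exact sums; the across-season statistics of the per-season
#' nest percentage use the sample SD (n - 1) and are rounded half-up to
#' integers, the printed precision.
#'
#' @param summaries Season-summary tibble ([summarize_season()] /
#'   [season_summaries()] output), one row per season.
#' @return One-row tibble: totals plus `pct_nests_mean`, `pct_nests_sd`
#'   (NA for a single season), `pct_nests_min`, `pct_nests_max`.
#' @export
#' @examples
#' swift_colony_counts() |>
#'   dplyr::filter(year <= 2015) |>
#'   season_summaries() |>
#'   pool_seasons()
pool_seasons <- function(summaries) {
  if (nrow(summaries) < 1L) stop_invalid("Need at least one season summary.")
  p <- summaries$pct_nests_with_drop
  tibble::tibble(
    n_seasons = nrow(summaries),
    total_observations = sum(summaries$n_observations),
    total_nights_with_drops = sum(summaries$n_nights_with_drops),
    total_nests_observed = sum(summaries$n_nests_observed),
    pct_nests_mean = round_half_up(mean(p), 0),
    pct_nests_sd = if (length(p) > 1L) round_half_up(sd(p), 0) else NA_real_,
    pct_nests_min = min(p),
    pct_nests_max = max(p)
  )
}

#' Descriptive statistics of drop events
#'
#' Mean, SD and range of event magnitude (degrees C) and duration (hours)
#' at 1-decimal rounding. An empty event set returns an empty tibble.
#'
#' @param events Drop-event tibble.
#' @return Tibble with one row per statistic set (`variable`, `n`, `mean`,
#'   `sd`, `min`, `max`).
#' @export
describe_events <- function(events) {
  if (nrow(events) == 0L) {
    return(tibble::tibble(variable = character(), n = integer(),
                          mean = numeric(), sd = numeric(),
                          min = numeric(), max = numeric()))
  }
  one <- function(nm, x) {
    x <- x[is.finite(x)]
    tibble::tibble(variable = nm, n = length(x),
                   mean = round_half_up(mean(x), 1),
                   sd = if (length(x) > 1L) round_half_up(sd(x), 1) else NA_real_,
                   min = round_half_up(min(x), 1),
                   max = round_half_up(max(x), 1))
  }
  dur <- events$duration
  if ("gapped" %in% names(events)) dur <- dur[!events$gapped]
  dplyr::bind_rows(one("magnitude_c", events$magnitude),
                   one("duration_h", dur))
}

#' Pearson product-moment correlation with two-sided p-value
#'
#' Thin wrapper over [stats::cor.test()] returning a tibble; errors on
#' degenerate inputs rather than returning NA.
#'
#' @param x,y Equal-length numeric vectors (n >= 3, finite values).
#' @return One-row tibble: `r`, `p`, `n`, `df`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("`x` and `y` must have equal length.")
  if (length(x) < 3L) stop_invalid("Need at least 3 paired observations.")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_invalid("Inputs must be finite.")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation undefined: zero variance input.",
          class = "torpr_undefined_correlation")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value,
                 n = length(x), df = unname(ct$parameter))
}

#' Mixed-model ambient-temperature contrast between torpor and non-torpor days
#'
#' For each response (daily mean/min/max ambient temperature), fits a
#' linear mixed model `response ~ group` with random intercepts for year
#' and nest, and reports group means with confidence intervals, the group
#' p-value and the marginal R-squared (variance explained by the fixed
#' effect over total modelled variance). When the random-effect variances
#' collapse to zero the point estimates coincide with the ordinary
#' two-group linear model.
#'
#' @param day_records Tibble with one row per measurement day: the response
#'   columns, a logical `torpor` column (status of the *following* night),
#'   and `year` and `nest_id` grouping columns. Incomplete first/last
#'   measurement days should be excluded by the caller.
#' @param responses Response column names.
#' @param conf Confidence level.
#' @return An object of class `torpr_contrast`; its `table` element (also
#'   returned by [tidy()]) has one row per response x group with `mean`,
#'   `ci_lo`, `ci_hi`, `n`, `r2_marginal`, `p_value`.
#' @export
#' @examples
#' days <- simulate_day_records(seed = 42)
#' tidy(contrast_ambient(days))
contrast_ambient <- function(day_records,
                             responses = c("mean_ta", "min_ta", "max_ta"),
                             conf = 0.95) {
  if (!"torpor" %in% names(day_records)) {
    stop_invalid("`day_records` must contain a logical `torpor` column.")
  }
  g <- factor(ifelse(day_records$torpor, "torpor", "no_torpor"),
              levels = c("no_torpor", "torpor"))
  if (any(table(g) == 0L)) {
    abort("Both torpor and non-torpor days are required.",
          class = "torpr_contrast_error")
  }
  dat <- day_records
  dat$.group <- g
  dat$year <- factor(dat$year)
  dat$nest_id <- factor(dat$nest_id)

  fit_one <- function(resp) {
    if (!resp %in% names(dat)) stop_invalid(paste0("Missing response `", resp, "`."))
    fml <- as.formula(paste(resp, "~ .group + (1 | year) + (1 | nest_id)"))
    ctrl <- lme4::lmerControl(
      check.nobs.vs.nlev = "ignore", check.nobs.vs.rankZ = "ignore",
      check.nobs.vs.nRE = "ignore",
      check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4)
    )
    m <- suppressMessages(suppressWarnings(
      lmerTest::lmer(fml, data = dat, REML = TRUE, control = ctrl)
    ))
    sm <- suppressWarnings(summary(m))
    p <- sm$coefficients[".grouptorpor", "Pr(>|t|)"]
    em <- suppressMessages(suppressWarnings(
      emmeans::emmeans(m, ".group", lmer.df = "satterthwaite")
    ))
    es <- as.data.frame(summary(em, level = conf))
    vc <- as.data.frame(lme4::VarCorr(m))
    var_re <- sum(vc$vcov[vc$grp != "Residual"])
    var_res <- vc$vcov[vc$grp == "Residual"]
    var_fix <- var(stats::predict(m, re.form = NA))
    r2m <- var_fix / (var_fix + var_re + var_res)
    tab <- tibble::tibble(
      response = resp,
      group = as.character(es$.group),
      mean = es$emmean, ci_lo = es$lower.CL, ci_hi = es$upper.CL,
      n = as.integer(table(g)[as.character(es$.group)]),
      r2_marginal = r2m,
      p_value = p
    )
    list(model = m, table = tab)
  }

  fits <- purrr::map(responses, fit_one)
  structure(list(
    table = dplyr::bind_rows(purrr::map(fits, "table")),
    models = setNames(purrr::map(fits, "model"), responses),
    n = nrow(dat), conf = conf
  ), class = "torpr_contrast")
}

#' @export
print.torpr_contrast <- function(x, ...) {
  cat(sprintf("<torpr_contrast> %d days, %g%% CIs\n", x$n, 100 * x$conf))
  print(x$table)
  invisible(x)
}

#' @rdname contrast_ambient
#' @param x A `torpr_contrast` object.
#' @param ... Unused.
#' @method tidy torpr_contrast
#' @export
tidy.torpr_contrast <- function(x, ...) x$table

#' @rdname contrast_ambient
#' @method glance torpr_contrast
#' @export
glance.torpr_contrast <- function(x, ...) {
  x$table |>
    dplyr::distinct(.data$response, .data$r2_marginal, .data$p_value) |>
    dplyr::mutate(n = x$n, conf = x$conf)
}
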