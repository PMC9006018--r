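# Whole-nest respirometry scoring: arrival peak, MR_ref / MR_min, relative
# reduction, bout timing against sun times, and torpor classification.
# All quantities describe the pooled nest occupancy, not individuals.

#' Locate the arrival peak in a night's VO2 trace
#'
#' The adults' return to the nest shows as a steep VO2 increase near
#' sunset. The peak is the maximum of the 5-min moving-average trace within
#' `search_window` minutes of sunset, provided it exceeds the pre-window
#' median by `prominence`; otherwise the night is flagged `"no arrival"`
#' and a fixed fallback reference time (sunset + 30 min) is used. Ties go
#' to the earlier sample.
#'
#' @param trace Gas-trace tibble (`timestamp`, `vo2`).
#' @param sun One row of [sun_times()] output for the night.
#' @param search_window Half-width of the search window around sunset,
#'   minutes.
#' @param smooth Moving-average window, minutes.
#' @param prominence Required ratio of peak to pre-window median.
#' @return One-row tibble: `peak_time`, `peak_vo2`, `arrival_detected`.
#' @export
detect_arrival_peak <- function(trace, sun, search_window = 90,
                                smooth = 5, prominence = 1.3) {
  sunset <- sun$sunset[1]
  w_lo <- sunset - search_window * 60
  w_hi <- sunset + search_window * 60
  if (min(trace$timestamp) > w_lo || max(trace$timestamp) < w_hi) {
    abort("Trace does not cover the arrival search window.",
          class = "torpr_coverage_error")
  }
  interval <- median(diff(as.numeric(trace$timestamp))) / 60
  s <- roll_mean(trace$vo2, max(1L, round(smooth / interval)))
  in_win <- trace$timestamp >= w_lo & trace$timestamp <= w_hi
  pre <- trace$timestamp >= w_lo - 60 * 60 & trace$timestamp < w_lo
  pre_med <- if (any(pre)) median(s[pre]) else median(s[in_win])
  peak_i <- which(in_win)[which.max(s[in_win])] # which.max: earlier tie wins
  detected <- is.finite(pre_med) && pre_med > 0 &&
    s[peak_i] >= prominence * pre_med
  if (!detected) {
    return(tibble::tibble(peak_time = sunset + 30 * 60,
                          peak_vo2 = NA_real_, arrival_detected = FALSE))
  }
  tibble::tibble(peak_time = trace$timestamp[peak_i], peak_vo2 = s[peak_i],
                 arrival_detected = TRUE)
}

#' Score one instrumented nest-night
#'
#' Computes the night's metabolic summary from the smoothed VO2 trace:
#' * `mr_ref`: the value half an hour after the arrival peak (the family is
#'   at rest by then);
#' * `mr_min`: the lowest value between `peak + 30 min` and sunrise;
#' * `reduction_pct = (mr_ref - mr_min) * 100 / mr_ref`;
#' * `onset_time`: start of the sustained decline (first time below
#'   `onset_factor * mr_ref` held for `onset_persist` minutes, tracked back
#'   to the decline's local start);
#' * `arousal_end_time`: first recovery above `onset_factor * mr_ref` after
#'   the minimum (trace end, flagged `arousal_truncated`, if never);
#' * bout timing relative to sunset/sunrise (positive `onset_vs_sunset` =
#'   after sunset; positive `end_vs_sunrise` = before sunrise).
#'
#' @param trace Gas-trace tibble (`timestamp`, `vo2`, optionally `vco2`,
#'   `nest_id`, `night_date`).
#' @param sun One row of [sun_times()] output.
#' @param peak Optional result of [detect_arrival_peak()]; computed when
#'   missing.
#' @param smooth Moving-average window (minutes) for the reference value.
#'   The raw point value would inherit full sensor noise; the window is
#'   exposed so the sensitivity can be examined.
#' @param min_smooth Moving-average window (minutes) for the nocturnal
#'   minimum, onset and arousal tracking. Wider than `smooth` because the
#'   minimum of a noisy series carries a downward extreme-value bias that
#'   shrinks with the averaging window.
#' @param onset_factor Fraction of `mr_ref` defining sustained decline and
#'   arousal recovery.
#' @param onset_persist Persistence required below the onset threshold,
#'   minutes.
#' @return One-row tibble (`NightScore`): identifiers, `peak_time`,
#'   `arrival_detected`, `mr_ref`, `mr_min`, `mr_min_time`,
#'   `reduction_pct`, `onset_time`, `onset_vs_sunset`, `arousal_end_time`,
#'   `end_vs_sunrise`, `arousal_truncated`, `bout_duration` (hours),
#'   `rer_mean`.
#' @export
score_night <- function(trace, sun, peak = NULL, smooth = 15,
                        min_smooth = 30, onset_factor = 0.9,
                        onset_persist = 30) {
  sunset <- sun$sunset[1]
  sunrise <- sun$next_sunrise[1]
  if (is.null(peak)) peak <- detect_arrival_peak(trace, sun)
  ref_time <- peak$peak_time[1] + 30 * 60
  if (max(trace$timestamp) < sunrise || min(trace$timestamp) > ref_time) {
    abort("Trace must span the reference time through sunrise.",
          class = "torpr_coverage_error")
  }
  interval <- median(diff(as.numeric(trace$timestamp))) / 60
  s_ref <- roll_mean(trace$vo2, max(1L, round(smooth / interval)))
  s <- roll_mean(trace$vo2, max(1L, round(min_smooth / interval)))
  tnum <- as.numeric(trace$timestamp)

  ref_i <- which.min(abs(tnum - as.numeric(ref_time)))
  mr_ref <- s_ref[ref_i]
  if (!is.finite(mr_ref) || mr_ref <= 0) {
    abort("Non-positive reference metabolic rate.", class = "torpr_trace_error")
  }
  win <- trace$timestamp > ref_time & trace$timestamp <= sunrise
  if (!any(win)) {
    abort("No samples between reference time and sunrise.",
          class = "torpr_coverage_error")
  }
  min_i <- which(win)[which.min(s[win])]
  mr_min <- s[min_i]
  reduction <- (mr_ref - mr_min) * 100 / mr_ref

  thr <- onset_factor * mr_ref
  need <- max(1L, ceiling(onset_persist / interval))
  onset_i <- sustained_below(s, thr, from = ref_i, need = need)
  onset_time <- as.POSIXct(NA, tz = "UTC")
  if (!is.na(onset_i)) {
    j <- onset_i
    while (j > ref_i && s[j - 1L] >= s[j]) j <- j - 1L
    onset_time <- trace$timestamp[j]
  }

  arousal_end <- as.POSIXct(NA, tz = "UTC")
  truncated <- NA
  if (!is.na(onset_i)) {
    after <- which(seq_along(s) > min_i & s >= thr)
    if (length(after) > 0L) {
      arousal_end <- trace$timestamp[after[1]]
      truncated <- FALSE
    } else {
      arousal_end <- trace$timestamp[length(s)]
      truncated <- TRUE
    }
  }

  tibble::tibble(
    nest_id = if ("nest_id" %in% names(trace)) trace$nest_id[1] else "nest",
    night_date = if ("night_date" %in% names(trace) &&
                     !is.na(trace$night_date[1])) trace$night_date[1] else
                       sun$date[1],
    peak_time = peak$peak_time[1],
    arrival_detected = isTRUE(peak$arrival_detected[1]),
    mr_ref = mr_ref, mr_min = mr_min, mr_min_time = trace$timestamp[min_i],
    reduction_pct = reduction,
    onset_time = onset_time,
    onset_vs_sunset = mins_between(onset_time, sunset),
    arousal_end_time = arousal_end,
    end_vs_sunrise = mins_between(sunrise, arousal_end),
    arousal_truncated = truncated,
    bout_duration = ifelse(is.na(onset_time) | is.na(arousal_end), NA_real_,
                           hours_between(arousal_end, onset_time)),
    rer_mean = if (all(is.finite(trace$vco2 %||% NA_real_))) {
      respiratory_quotient(trace)$rer_mean
    } else NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# First index from which x stays below `thr` for `need` consecutive samples.
sustained_below <- function(x, thr, from, need) {
  below <- x < thr
  below[seq_len(min(from, length(x)))] <- FALSE
  r <- run_bounds(below)
  r <- r[r$end - r$start + 1L >= need, , drop = FALSE]
  if (nrow(r) == 0L) NA_integer_ else r$start[1]
}

#' Score every instrumented nest-night in a gas table
#'
#' Convenience wrapper mapping [score_night()] over `nest_id` x
#' `night_date` groups; nights whose trace cannot be scored (insufficient
#' coverage) are skipped with a warning.
#'
#' @param gas Long gas tibble (`timestamp`, `vo2`, `vco2`, `nest_id`,
#'   `night_date`).
#' @param sun [sun_times()] tibble covering the nights.
#' @param ... Passed to [score_night()].
#' @return Tibble of night scores.
#' @export
score_gas_nights <- function(gas, sun, ...) {
  groups <- dplyr::distinct(gas, .data$nest_id, .data$night_date)
  res <- purrr::pmap(list(groups$nest_id, groups$night_date),
    function(id, nd) {
      tr <- gas[gas$nest_id == id & gas$night_date == nd, ]
      sn <- sun[sun$date == nd, ]
      if (nrow(sn) == 0L) return(NULL)
      tryCatch(score_night(tr, sn, ...),
               torpr_coverage_error = function(e) {
                 warn(sprintf("Skipping %s / %s: %s", id, nd, conditionMessage(e)))
                 NULL
               })
    })
  dplyr::bind_rows(purrr::compact(res))
}

#' Attach nest-temperature drop events to night scores
#'
#' Joins each night score with the (at most one, after nightly
#' deduplication) drop event of the same nest-night, adding the drop
#' magnitude (`tnest_drop`) and the thermal lag `tnest_lag_min` =
#' minutes from VO2 decline onset to T_nest decline start (positive lag =
#' thermal inertia). Nights without an event keep `NA` fields and can only
#' be classified MR-only.
#'
#' @param scores Night-score tibble from [score_night()].
#' @param events Drop events from [detect_drops()].
#' @return `scores` with `tnest_drop`, `tnest_lag_min`, `has_drop`.
#' @export
link_tnest <- function(scores, events) {
  key <- paste(events$nest_id, events$night_date)
  if (anyDuplicated(key)) {
    stop_invalid("Multiple drop events per nest-night; deduplicate first.")
  }
  idx <- match(paste(scores$nest_id, scores$night_date), key)
  scores$tnest_drop <- events$magnitude[idx]
  scores$tnest_lag_min <- mins_between(events$start_time[idx], scores$onset_time)
  scores$has_drop <- !is.na(idx)
  scores
}

#' Classify torpor nights from MR reduction and the linked thermal drop
#'
#' A night is torpid when `reduction_pct >= threshold` (boundary included)
#' AND, when nest-temperature data are available (`has_drop` column
#' present), a substantial drop event is linked to the same nest-night.
#' Nights lacking temperature coverage are classified MR-only and flagged.
#' The default threshold is the conservative ~50% whole-group guideline; a
#' `"replication"` preset uses 48 so a 49% night still counts as torpor
#' under the "approximately 50%" reading.
#'
#' @param scores Night-score tibble (after [link_tnest()] if temperature
#'   data exist).
#' @param threshold Reduction threshold in percent, or `"replication"`.
#' @param require_drop Require a linked drop event when drop information is
#'   present?
#' @return `scores` with added `torpor` flag and `mr_only` flag.
#' @export
classify_torpor <- function(scores, threshold = 50, require_drop = TRUE) {
  if (identical(threshold, "replication")) threshold <- 48
  check_number(threshold, "threshold", 0, 100)
  meets <- scores$reduction_pct >= threshold
  if (require_drop && "has_drop" %in% names(scores)) {
    scores$torpor <- meets & scores$has_drop
    scores$mr_only <- FALSE
  } else {
    scores$torpor <- meets
    scores$mr_only <- TRUE
  }
  scores
}

#' Mean respiratory exchange ratio of a trace
#'
#' Mean of `vco2 / vo2` over the window, excluding samples with VO2 at or
#' below `vo2_floor` (the ratio is unstable near zero flow). Reported as
#' supporting output only.
#'
#' @param trace Gas-trace tibble with `vo2` and `vco2`.
#' @param window Optional POSIXct length-2 vector restricting the samples.
#' @param vo2_floor Exclusion floor for VO2.
#' @return One-row tibble: `rer_mean`, `n_used`, `n_excluded`.
#' @export
respiratory_quotient <- function(trace, window = NULL, vo2_floor = 1e-6) {
  if (!"vco2" %in% names(trace) || all(is.na(trace$vco2))) {
    abort("`vco2` is absent from this trace.", class = "torpr_unsupported_input")
  }
  sel <- rep(TRUE, nrow(trace))
  if (!is.null(window)) {
    sel <- trace$timestamp >= window[1] & trace$timestamp <= window[2]
  }
  ok <- sel & !is.na(trace$vo2) & !is.na(trace$vco2) & trace$vo2 > vo2_floor
  tibble::tibble(
    rer_mean = mean(trace$vco2[ok] / trace$vo2[ok]),
    n_used = sum(ok), n_excluded = sum(sel) - sum(ok)
  )
}
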