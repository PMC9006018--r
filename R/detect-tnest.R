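# Nest-temperature torpor indicator: occupancy inference, drop-event
# segmentation against the ambient-referenced criterion, and the
# torpor-cycle shape score.

#' Infer nightly nest occupancy from thermal elevation
#'
#' A night is scored occupied when the mean nocturnal `T_nest - T_a`
#' exceeds `threshold` (occupants heat the nest), or when a detected drop
#' event spans the night (a drop implies prior warming). Nights with less
#' than `min_coverage` of their expected samples give `occupied = NA`
#' (unknown) and are excluded from denominators downstream.
#'
#' @param nest,ambient Temperature-trace tibbles.
#' @param nights Night windows from [night_window()] (or a [sun_times()]
#'   tibble, converted internally).
#' @param threshold Mean nocturnal elevation (degrees C) defining occupancy.
#' @param min_coverage Minimum fraction of expected nocturnal samples.
#' @param events Optional [detect_drops()] output; a night spanned by an
#'   event counts as occupied regardless of mean elevation.
#' @return Tibble `nest_id`, `night_date`, `occupied`, `mean_diff`,
#'   `coverage`.
#' @export
infer_occupancy <- function(nest, ambient, nights, threshold = 3,
                            min_coverage = 0.5, events = NULL) {
  if (!"start" %in% names(nights)) nights <- night_window(nights)
  paired <- align_traces(nest, ambient)
  interval <- median(diff(as.numeric(nest$timestamp))) / 60
  nid <- if ("source_id" %in% names(nest)) nest$source_id[1] else "nest"

  per_night <- purrr::pmap(
    list(nights$night_date, nights$start, nights$end),
    function(nd, s, e) {
      sel <- paired$timestamp >= s & paired$timestamp < e
      expected <- max(1, floor(as.numeric(difftime(e, s, units = "mins")) / interval))
      cov <- sum(sel) / expected
      md <- if (any(sel)) mean(paired$diff[sel]) else NA_real_
      occ <- if (cov < min_coverage) NA else md > threshold
      tibble::tibble(nest_id = nid, night_date = nd, occupied = occ,
                     mean_diff = md, coverage = cov)
    }
  )
  out <- dplyr::bind_rows(per_night)
  if (!is.null(events) && nrow(events) > 0L) {
    ev_nights <- unique(events$night_date[events$nest_id == nid])
    out$occupied[out$night_date %in% ev_nights] <- TRUE
  }
  out
}

#' Select nests continuously occupied long enough for season statistics
#'
#' A nest qualifies when its longest run of consecutive occupied nights
#' (consecutive calendar dates, `occupied = TRUE`) reaches `min_nights`.
#' Each selected nest contributes its occupied-night count to the season's
#' observation total (observations = sum of occupied nights).
#'
#' @param occupancy Tibble from [infer_occupancy()] (any number of nests).
#' @param min_nights Minimum consecutive occupied nights (default 30).
#' @return Tibble `nest_id`, `n_occupied_nights`, `longest_run`, `selected`.
#' @export
select_monitored_nests <- function(occupancy, min_nights = 30L) {
  occupancy |>
    dplyr::group_by(.data$nest_id) |>
    dplyr::arrange(.data$night_date, .by_group = TRUE) |>
    dplyr::summarise(
      n_occupied_nights = sum(.data$occupied %in% TRUE),
      longest_run = longest_consecutive_run(.data$night_date, .data$occupied),
      .groups = "drop"
    ) |>
    dplyr::mutate(selected = .data$longest_run >= min_nights)
}

# Longest run of occupied = TRUE on consecutive calendar dates.
longest_consecutive_run <- function(dates, occupied) {
  occ_dates <- sort(dates[occupied %in% TRUE])
  if (length(occ_dates) == 0L) return(0L)
  gaps <- c(TRUE, diff(occ_dates) != 1)
  max(table(cumsum(gaps)))
}

#' Detect substantial nest-temperature drops
#'
#' Implements the ambient-referenced drop criterion: maximal runs of
#' samples with `T_nest - T_a <= criterion` are located, runs closer than
#' `merge_gap` minutes are merged, and runs shorter than `min_persist`
#' minutes are discarded (single-sample crossings are unreliable at logger
#' accuracy). A run must be *entered from above* the criterion (a genuine
#' downward crossing); runs that begin below it -- e.g. a vacant nest, or
#' the warm-up right after arrival -- are not drops. Each surviving run is
#' extended backwards along the smoothed trace to the local maximum where
#' the continuous decline began (the drop's start value is read there), and
#' forwards to recovery (first return within `recovery_margin` degrees C of
#' the start value, else trace end). Events are scored against the
#' torpor-cycle shape template ([shape_score()]) and, when `nights` is
#' given, restricted to criterion crossings inside night windows and
#' deduplicated to at most one event per nest-night (deepest kept).
#'
#' @param nest,ambient Temperature-trace tibbles.
#' @param criterion Drop criterion in degrees C (> 0): a sample is "below"
#'   when `T_nest - T_a <= criterion`. Default 7.
#' @param nights Optional night windows ([night_window()] or [sun_times()]
#'   output); when supplied, only nocturnal crossings count and events get
#'   `night_date` from their window.
#' @param min_persist Minimum below-criterion persistence, minutes.
#' @param merge_gap Merge below-runs separated by less than this, minutes.
#' @param recovery_margin Recovery completes when the smoothed `T_nest`
#'   returns within this many degrees C of its start value, or when the
#'   smoothed elevation `T_nest - T_a` returns above
#'   `criterion + recovery_margin` (an arousal restores the elevation even
#'   if a cold snap keeps the absolute temperature low).
#' @param smooth_window Running-median window (minutes) used for boundary
#'   extension ("decreased continuously" is evaluated on the smoothed
#'   trace).
#' @param decline_tol Tolerated uphill step (degrees C) during the backward
#'   decline extension; absorbs logger quantization.
#' @param min_score Shape-score threshold below which an event is rejected
#'   as a non-torpor artefact.
#' @param end_cap_h Maximum hours past the below-criterion run within which
#'   recovery is sought; beyond it the event is closed where the search
#'   stopped (a cold spell can defer full recovery for days).
#' @param keep_rejected Keep rejected events (flagged `accepted = FALSE`)?
#' @param dedup Deduplicate to at most one event per nest-night (deepest
#'   kept)? Disable only for diagnostics such as comparing raw segmentation
#'   against an oracle.
#' @param timezone_offset Hours east of UTC, used to attribute events to
#'   the calendar date of their sunset when `nights` is not supplied.
#' @return Tibble of drop events: `nest_id`, `night_date`, `start_time`,
#'   `criterion_time`, `end_time`, `magnitude`, `duration` (hours),
#'   `min_tnest`, `min_diff`, `shape_score`, `accepted`, `gapped`,
#'   `n_samples`.
#' @export
detect_drops <- function(nest, ambient, criterion = 7, nights = NULL,
                         min_persist = 30, merge_gap = 30,
                         recovery_margin = 2, smooth_window = 15,
                         decline_tol = 0.25, min_score = 0.5, end_cap_h = 12,
                         keep_rejected = FALSE, dedup = TRUE,
                         timezone_offset = 0) {
  if (!is.numeric(criterion) || criterion <= 0) {
    stop_invalid("`criterion` must be a positive temperature difference.")
  }
  if (!is.null(nights) && !"start" %in% names(nights)) {
    nights <- night_window(nights)
  }
  paired <- align_traces(nest, ambient)
  n <- nrow(paired)
  empty <- empty_events()
  if (n < 2L) return(empty)
  interval <- median(diff(as.numeric(paired$timestamp))) / 60
  min_len <- max(1L, ceiling(min_persist / interval))
  nid <- paired$nest_id[1]
  if (is.na(nid)) nid <- "nest"

  below <- !is.na(paired$diff) & paired$diff <= criterion
  runs <- run_bounds(below)
  if (nrow(runs) == 0L) return(empty)

  # merge runs separated by short above-criterion interludes
  if (nrow(runs) > 1L) {
    gap_min <- (as.numeric(paired$timestamp[runs$start[-1]]) -
                  as.numeric(paired$timestamp[runs$end[-nrow(runs)]])) / 60
    grp <- cumsum(c(TRUE, gap_min >= merge_gap))
    runs <- tibble::tibble(
      start = as.integer(tapply(runs$start, grp, min)),
      end = as.integer(tapply(runs$end, grp, max))
    )
  }

  runs <- runs[(runs$end - runs$start + 1L) >= min_len, , drop = FALSE]
  if (nrow(runs) == 0L) return(empty)
  # downward crossing: the run must be entered from above the criterion
  crossed <- runs$start > 1L & !is.na(paired$diff[pmax(runs$start - 1L, 1L)]) &
    paired$diff[pmax(runs$start - 1L, 1L)] > criterion
  runs <- runs[crossed, , drop = FALSE]
  if (nrow(runs) == 0L) return(empty)

  smooth_k <- max(1L, round(smooth_window / interval))
  s <- roll_median(paired$t_nest, smooth_k)
  s_diff <- roll_median(paired$diff, smooth_k)

  events <- purrr::pmap(list(runs$start, runs$end), function(rs, re) {
    # backward extension through the (tolerance-smoothed) decline ...
    j <- rs
    while (j > 1L && s[j - 1L] >= s[j] - decline_tol &&
           (as.numeric(paired$timestamp[rs]) -
              as.numeric(paired$timestamp[j - 1L])) / 60 <= 720) {
      j <- j - 1L
    }
    # ... then forward to the last point still at the pre-decline maximum:
    # on a flat-topped curve the continuous decline starts at the plateau's
    # trailing edge, not its leading edge
    seg_max <- max(s[j:rs])
    j <- j + max(which(s[j:rs] >= seg_max - decline_tol)) - 1L
    start_val <- s[j] # smoothed: a single noisy sample must not end an event
    # forward extension to recovery, capped at `end_cap_h` hours past the
    # below-criterion run (cold spells can defer full recovery for days)
    m <- re
    cap_t <- as.numeric(paired$timestamp[re]) + end_cap_h * 3600
    while (m < n && s[m] < start_val - recovery_margin &&
           s_diff[m] < criterion + recovery_margin &&
           as.numeric(paired$timestamp[m + 1L]) <= cap_t) m <- m + 1L
    seg <- paired[j:m, ]
    gapped <- any(diff(as.numeric(seg$timestamp)) / 60 > 30)
    min_i <- which.min(seg$t_nest)
    tibble::tibble(
      nest_id = nid,
      start_time = seg$timestamp[1],
      criterion_time = paired$timestamp[rs],
      end_time = seg$timestamp[nrow(seg)],
      magnitude = start_val - seg$t_nest[min_i],
      duration = hours_between(seg$timestamp[nrow(seg)], seg$timestamp[1]),
      min_tnest = seg$t_nest[min_i],
      min_diff = min(paired$diff[rs:re]),
      shape_score = shape_score(seg, criterion = criterion)$score,
      gapped = gapped,
      n_samples = nrow(seg)
    )
  })
  events <- dplyr::bind_rows(events)

  # night attribution
  if (!is.null(nights)) {
    idx <- purrr::map_int(seq_len(nrow(events)), function(k) {
      w <- which(events$criterion_time[k] >= nights$start &
                   events$criterion_time[k] < nights$end)
      if (length(w) == 0L) NA_integer_ else w[1]
    })
    events$night_date <- nights$night_date[idx]
    events <- events[!is.na(idx), , drop = FALSE]
  } else {
    events$night_date <- night_date_of(events$criterion_time, timezone_offset)
  }

  events$accepted <- events$shape_score >= min_score
  if (!keep_rejected) events <- events[events$accepted, , drop = FALSE]
  if (nrow(events) == 0L) return(empty)

  # one event per night: keep the deepest
  if (dedup) {
    events <- events |>
      dplyr::group_by(.data$nest_id, .data$night_date) |>
      dplyr::arrange(dplyr::desc(.data$magnitude), .by_group = TRUE) |>
      dplyr::slice(1L) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$start_time)
  }
  events[, c("nest_id", "night_date", "start_time", "criterion_time",
             "end_time", "magnitude", "duration", "min_tnest", "min_diff",
             "shape_score", "accepted", "gapped", "n_samples")]
}

empty_events <- function() {
  tibble::tibble(
    nest_id = character(), night_date = as.Date(character()),
    start_time = as.POSIXct(character(), tz = "UTC"),
    criterion_time = as.POSIXct(character(), tz = "UTC"),
    end_time = as.POSIXct(character(), tz = "UTC"),
    magnitude = numeric(), duration = numeric(), min_tnest = numeric(),
    min_diff = numeric(), shape_score = numeric(), accepted = logical(),
    gapped = logical(), n_samples = integer()
  )
}

# Start/end indices of TRUE runs.
run_bounds <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble::tibble(start = starts[r$values], end = ends[r$values])
}

#' Score a drop event against the torpor-cycle shape template
#'
#' Composite of three sub-scores in `[0, 1]`, averaged, all evaluated on a
#' running-median-smoothed copy of the segment (raw logger noise would
#' dominate step-wise statistics):
#' * entry: fraction of non-increasing steps of the smoothed trace over
#'   the cooling ramp (start until the raw trace first comes within 2
#'   degrees C of the event minimum), rescaled above chance level -- an
#'   uncorrelated noisy trace declines on about half its steps by symmetry,
#'   so the raw fraction `f` maps to `max(0, 2 f - 1)`. A torpor entry
#'   cools over an extended period; if the ramp is shorter than an hour
#'   the sub-score is 0 (a step drop has no entry phase, and noise jumps
#'   into its minimum band almost immediately).
#' * plateau stability: fraction of below-criterion samples within 2
#'   degrees C of the event minimum (raw trace);
#' * rewarming: mean rewarming slope at least half the mean cooling slope
#'   scores 1 (a torpor arousal rewarms *faster* than entry cools), but
#'   only if the arousal actually restored the nest's elevation above the
#'   criterion (trailing `T_nest - T_a` back above `criterion + 1`, an
#'   ambient-referenced gate robust to overnight cold-snap arrivals) -- step cooling with no rewarming (a departing
#'   bird) and noise wandering around the criterion both score 0 here.
#'
#' Events shorter than 12 samples score 0 and are flagged `"short"`.
#'
#' @param segment Event segment: tibble with `timestamp`, `t_nest` and
#'   `diff` columns (as cut from [align_traces()] output).
#' @param criterion Criterion used for the plateau and rewarming
#'   sub-scores.
#' @param decline_tol Tolerated uphill step during entry, degrees C.
#' @param min_entry_min Minimum cooling-phase length (minutes) for a
#'   non-zero entry sub-score.
#' @return One-row tibble: `score`, `entry_score`, `plateau_score`,
#'   `rewarm_score`, `flag`.
#' @export
shape_score <- function(segment, criterion = 7, decline_tol = 0.25,
                        min_entry_min = 60) {
  n <- nrow(segment)
  if (n < 12L) {
    return(tibble::tibble(score = 0, entry_score = 0, plateau_score = 0,
                          rewarm_score = 0, flag = "short"))
  }
  x <- roll_median(segment$t_nest, 3L)
  t_h <- as.numeric(segment$timestamp) / 3600
  min_i <- which.min(x)
  raw_min <- min(segment$t_nest)
  ramp_end <- which(segment$t_nest <= raw_min + 2)[1]
  entry <- if (ramp_end > 1L && (t_h[ramp_end] - t_h[1]) * 60 >= min_entry_min) {
    f <- mean(diff(x[1:ramp_end]) <= 0)
    max(0, 2 * f - 1)
  } else 0
  below <- !is.na(segment$diff) & segment$diff <= criterion
  plateau <- if (any(below)) mean(segment$t_nest[below] <= raw_min + 2) else 0
  cool_rate <- if (min_i > 1L) (x[1] - x[min_i]) / (t_h[min_i] - t_h[1]) else NA
  tail_val <- mean(x[max(1L, n - 2L):n])
  rearoused <- mean(segment$diff[max(1L, n - 2L):n], na.rm = TRUE) >= criterion + 1
  # rewarming starts where the minimum band is left for good, not at the
  # first minimum sample (the plateau lies between the two)
  min_last <- max(which(x <= x[min_i] + 0.25))
  rewarm <- if (!rearoused) {
    0
  } else if (!is.finite(cool_rate) || cool_rate <= 0) {
    1 # step cooling: any genuine re-arousal rewarms at least as fast
  } else if (min_last < n) {
    rw_rate <- (tail_val - x[min_last]) / (t_h[n] - t_h[min_last])
    if (rw_rate <= 0) 0 else min(1, rw_rate / (0.5 * cool_rate))
  } else 0
  tibble::tibble(
    score = mean(c(entry, plateau, rewarm)),
    entry_score = entry, plateau_score = plateau, rewarm_score = rewarm,
    flag = NA_character_
  )
}
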