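# Nest-temperature drop detection, occupancy, shape scoring.

test_that("an empty nest (T_nest = T_a) is never occupied and yields no drops", {
  times <- five_min_grid(hours = 30)
  amb <- make_trace(times, 18 + rnorm(length(times), 0, 0.2), "amb", "ambient")
  nest <- make_trace(times, 18 + rnorm(length(times), 0, 0.2), "n1", "nest")
  sun <- colony_sun()
  occ <- infer_occupancy(nest, amb, sun)
  expect_false(any(occ$occupied))
  expect_equal(nrow(detect_drops(nest, amb)), 0L)
})

test_that("a nest warmed to the simulated occupied equilibrium is occupied", {
  # gamma * MR / lambda = 12 C above ambient
  times <- five_min_grid(hours = 30)
  amb <- make_trace(times, rep(18, length(times)), "amb", "ambient")
  nest <- make_trace(times, rep(30, length(times)), "n1", "nest")
  occ <- infer_occupancy(nest, amb, colony_sun())
  expect_true(all(occ$occupied))
  expect_equal(occ$mean_diff, 12, tolerance = 1e-10)
})

test_that("nights with insufficient coverage are unknown, not occupied", {
  sun <- colony_sun()
  times <- seq(sun$sunset, sun$sunset + 3600, by = 300) # 1 h of a 7.5 h night
  amb <- make_trace(times, rep(18, length(times)), "amb", "ambient")
  nest <- make_trace(times, rep(30, length(times)), "n1", "nest")
  occ <- infer_occupancy(nest, amb, sun)
  expect_true(is.na(occ$occupied))
})

test_that("occupancy on a synthetic season matches the generative labels", {
  cfg <- sim_config(n_nests = 4, n_instrumented = 0, occupied_fraction = 0.5,
                    torpor_probability = 0.2,
                    season_end = as.Date("2017-06-10"), seed = 21)
  sim <- simulate_season(cfg)
  nw <- night_window(sim$sun)
  occ <- dplyr::bind_rows(lapply(split(sim$nest_temp, sim$nest_temp$nest_id),
                                 function(tr) infer_occupancy(tr, sim$ambient, nw)))
  truth_occ <- dplyr::distinct(sim$truth, .data$nest_id, .data$occupied)
  merged <- dplyr::left_join(occ, truth_occ, by = "nest_id",
                             suffix = c("_detected", "_true"))
  expect_true(all(merged$occupied_detected == merged$occupied_true))
  expect_true(dplyr::n_distinct(truth_occ$occupied) == 2L) # both classes seen
})

test_that("the 30-consecutive-night rule is a strict boundary", {
  mk_occ <- function(flags) {
    tibble::tibble(nest_id = "n1",
                   night_date = as.Date("2017-06-01") + seq_along(flags) - 1,
                   occupied = flags)
  }
  # 29 consecutive nights: excluded
  sel <- select_monitored_nests(mk_occ(rep(TRUE, 29)))
  expect_false(sel$selected)
  # 30: included
  sel <- select_monitored_nests(mk_occ(rep(TRUE, 30)))
  expect_true(sel$selected)
  expect_equal(sel$n_occupied_nights, 30L)
  # 40 nights with a single-night gap (runs 20 + 19): excluded
  flags <- rep(TRUE, 40)
  flags[21] <- FALSE
  sel <- select_monitored_nests(mk_occ(flags))
  expect_false(sel$selected)
  expect_equal(sel$longest_run, 20L)
})

test_that("run-length counting matches a brute-force scan on random patterns", {
  set.seed(77)
  for (rep in 1:20) {
    n <- 50
    flags <- runif(n) < 0.7
    occ <- tibble::tibble(nest_id = "n1",
                          night_date = as.Date("2017-06-01") + 0:(n - 1),
                          occupied = flags)
    # brute force longest run
    best <- 0L
    cur <- 0L
    for (k in seq_len(n)) {
      cur <- if (flags[k]) cur + 1L else 0L
      best <- max(best, cur)
    }
    expect_equal(select_monitored_nests(occ)$longest_run, best)
  }
})

test_that("a flat warm nest yields no events; a square drop yields one", {
  times <- five_min_grid(hours = 24)
  amb <- make_trace(times, rep(18, length(times)), "amb", "ambient")
  warm <- make_trace(times, rep(33, length(times)), "n1", "nest")
  expect_equal(nrow(detect_drops(warm, amb)), 0L)

  sq <- square_drop(high = 15, low = 5, low_hours = 6)
  ev <- detect_drops(sq$nest, sq$ambient)
  expect_equal(nrow(ev), 1L)
  expect_gte(ev$duration, 6)
  expect_equal(ev$min_diff, 5)
  expect_equal(ev$magnitude, 10)
  expect_error(detect_drops(sq$nest, sq$ambient, criterion = -1),
               class = "torpr_invalid_arg")
})

test_that("flagged samples and event boundaries match the brute-force oracle", {
  set.seed(13)
  for (rep in 1:200) {
    times <- five_min_grid(hours = 20)
    n <- length(times)
    amb_c <- 18 + cumsum(rnorm(n, 0, 0.15))
    # random-walk nest trace wandering across the criterion
    nest_c <- amb_c + 10 + cumsum(rnorm(n, 0, 0.6))
    amb <- make_trace(times, amb_c, "amb", "ambient")
    nest <- make_trace(times, nest_c, "n1", "nest")
    diffs <- nest_c - amb_c

    # flagged-sample set from the aligned pairing vs per-sample thresholding
    flagged_oracle <- integer(0)
    for (i in seq_len(n)) if (diffs[i] <= 7) flagged_oracle <- c(flagged_oracle, i)
    expect_identical(which(align_traces(nest, amb)$diff <= 7), flagged_oracle)

    ev <- detect_drops(nest, amb, keep_rejected = TRUE, dedup = FALSE)
    orc <- oracle_runs(diffs, times, criterion = 7, min_len = 6,
                       merge_gap = 30)
    expect_equal(nrow(ev), nrow(orc))
    if (nrow(ev) > 0) {
      expect_equal(ev$criterion_time, times[orc$start])
      expect_equal(ev$min_diff, orc$min_diff)
    }
  }
})

test_that("more permissive criteria flag supersets of samples", {
  set.seed(5)
  times <- five_min_grid(hours = 20)
  n <- length(times)
  amb_c <- rep(18, n)
  nest_c <- 18 + 10 + cumsum(rnorm(n, 0, 0.5))
  flagged <- function(crit) sum(nest_c - amb_c <= crit)
  counts <- vapply(c(2, 5, 7, 9, 12), flagged, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("noise-free simulated torpor cycles score at least 0.9", {
  cfg <- sim_config(n_nests = 1, n_instrumented = 0, sensor_noise_sd = 0,
                    quantization = 0, ambient_noise_sd = 0,
                    cold_day_prob = 0, day_offset_sd = 0,
                    torpor_probability = 1,
                    season_end = as.Date("2017-06-07"), seed = 3)
  sim <- simulate_season(cfg)
  ev <- detect_drops(sim$nest_temp, sim$ambient,
                     nights = night_window(sim$sun))
  expect_equal(nrow(ev), 7L) # one per night
  expect_true(all(ev$shape_score >= 0.9))
})

test_that("step cooling without rewarming loses the rewarming sub-score", {
  times <- five_min_grid(hours = 12)
  n <- length(times)
  temp <- c(rep(30, 24), rep(20, n - 24)) # departure: cools, never rewarms
  seg_nest <- make_trace(times, temp)
  amb <- make_trace(times, rep(18, n), "amb", "ambient")
  seg <- align_traces(seg_nest, amb)
  ss <- shape_score(seg)
  expect_equal(ss$rewarm_score, 0)
  expect_lte(ss$score, 2 / 3)
})

test_that("events shorter than 12 samples score zero with a short flag", {
  times <- five_min_grid(hours = 1)[1:8]
  seg <- align_traces(make_trace(times, seq(30, 23, length.out = 8)),
                      make_trace(times, rep(18, 8), "amb", "ambient"))
  ss <- shape_score(seg)
  expect_equal(ss$score, 0)
  expect_equal(ss$flag, "short")
})

test_that("noise wandering at the criterion is rejected on >= 95% of nights", {
  set.seed(99)
  accepted <- 0L
  n_nights <- 1000L
  for (k in seq_len(n_nights)) {
    times <- five_min_grid(start = "2017-07-01 18:00:00", hours = 12)
    n <- length(times)
    amb <- make_trace(times, rep(18, n), "amb", "ambient")
    temp <- 18 + 7 + rnorm(n, 0, 1)
    temp[1:12] <- 28 # warm start so downward crossings exist
    nest <- make_trace(times, temp, "n1", "nest")
    if (nrow(detect_drops(nest, amb)) > 0L) accepted <- accepted + 1L
  }
  expect_lte(accepted / n_nights, 0.05)
})

test_that("drop detection recovers season ground truth with noise on", {
  cfg <- sim_config(n_nests = 6, n_instrumented = 0, torpor_probability = 0.25,
                    season_end = as.Date("2017-06-24"), seed = 11)
  sim <- simulate_season(cfg)
  nw <- night_window(sim$sun)
  ev <- dplyr::bind_rows(lapply(split(sim$nest_temp, sim$nest_temp$nest_id),
                                function(tr) detect_drops(tr, sim$ambient,
                                                          nights = nw)))
  det <- dplyr::mutate(ev[, c("nest_id", "night_date")], detected = TRUE)
  cmp <- dplyr::left_join(sim$truth, det, by = c("nest_id", "night_date"))
  cmp$detected[is.na(cmp$detected)] <- FALSE
  expect_gt(sum(cmp$torpor), 10) # the draw produced a usable sample
  expect_true(all(cmp$detected == cmp$torpor)) # sensitivity = specificity = 1
  # events per nest sum to the season total; one event per nest-night
  expect_equal(sum(table(ev$nest_id)), nrow(ev))
  expect_equal(anyDuplicated(paste(ev$nest_id, ev$night_date)), 0L)
  # start_time <= criterion_time < end_time, magnitude and duration positive
  expect_true(all(ev$start_time <= ev$criterion_time))
  expect_true(all(ev$criterion_time < ev$end_time))
  expect_true(all(ev$magnitude > 0))
  expect_true(all(ev$duration > 0))
  expect_true(all(ev$min_diff <= 7))
})
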