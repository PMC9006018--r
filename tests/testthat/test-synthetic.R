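# The synthetic-data generator: ambient forcing, gas-trace physiology,
# the Newtonian nest thermal model, and whole-season assembly.

test_that("config invariants are enforced", {
  expect_error(sim_config(torpid_fraction = 1.2), class = "torpr_invalid_arg")
  expect_error(sim_config(torpor_probability = -0.1), class = "torpr_invalid_arg")
  expect_error(sim_config(cooling_lambda = 0), class = "torpr_invalid_arg")
  expect_error(sim_config(nest_warming_gamma = -1), class = "torpr_invalid_arg")
  expect_error(sim_config(sample_interval = 0), class = "torpr_invalid_arg")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("degenerate ambient forcing gives a constant series", {
  cfg <- sim_config(ambient_amplitude = 0, ambient_noise_sd = 0,
                    cold_day_prob = 0, day_offset_sd = 0, ambient_mean = 18)
  amb <- simulate_ambient(cfg, n_days = 2, seed = 1)
  expect_true(all(amb$temp_c == 18))
  expect_equal(nrow(amb), 2 * 288)
})

test_that("ambient simulation is deterministic in the seed", {
  cfg <- sim_config()
  a <- simulate_ambient(cfg, n_days = 3, seed = 42)
  b <- simulate_ambient(cfg, n_days = 3, seed = 42)
  expect_identical(a, b)
  expect_error(simulate_ambient(cfg, n_days = 0), class = "torpr_invalid_arg")
})

test_that("residual SD around the sinusoid matches the generating noise", {
  cfg <- sim_config(ambient_noise_sd = 1, cold_day_prob = 0, day_offset_sd = 0)
  n_days <- ceiling(10000 / 288)
  amb <- simulate_ambient(cfg, n_days = n_days, seed = 7)
  start <- amb$timestamp[1]
  h <- ((as.numeric(amb$timestamp) - as.numeric(start)) / 3600) %% 24
  sinus <- cfg$ambient_mean +
    cfg$ambient_amplitude * cos(2 * pi * ((h %% 24) - 17) / 24)
  resid <- amb$temp_c - sinus
  expect_lt(abs(sd(resid) - 1), 0.05)
})

test_that("a non-torpor night bottoms out at the resting rate", {
  cfg <- sim_config(mr_noise_sd = 0)
  sun <- colony_sun()
  night <- simulate_mr_night(cfg, torpor = FALSE, sun = sun, seed = 1)
  tr <- night$trace
  post <- tr$timestamp > sun$sunset + 3600 & tr$timestamp < sun$next_sunrise
  expect_equal(min(tr$vo2[post]), cfg$resting_mr, tolerance = 1e-10)
  expect_identical(night$truth$true_reduction_pct, 0)
  expect_false(night$truth$torpor)
})

test_that("generative torpor depth is recovered by the night scorer", {
  cfg <- sim_config(mr_noise_sd = 0, torpid_fraction = 0.56)
  sun <- colony_sun()
  night <- simulate_mr_night(cfg, torpor = TRUE, sun = sun, seed = 1)
  sc <- score_night(night$trace, sun)
  expect_lt(abs(sc$reduction_pct - 56), 1)
  expect_lt(abs(night$truth$true_reduction_pct - 56), 1)
})

test_that("zero ramp time constants give an exact square-wave reduction", {
  cfg <- sim_config(mr_noise_sd = 0, torpid_fraction = 0.5,
                    entry_tau = 0, arousal_tau = 0, arrival_peak_height = 1)
  sun <- colony_sun()
  night <- simulate_mr_night(cfg, torpor = TRUE, sun = sun, seed = 1)
  tr <- night$trace
  plateau <- tr$timestamp > sun$sunset + cfg$entry_delay * 60 &
    tr$timestamp < sun$next_sunrise - (cfg$arousal_lead + 1) * 60
  expect_true(all(tr$vo2[plateau] == cfg$resting_mr * 0.5))
  peak <- tibble::tibble(peak_time = sun$sunset + cfg$arrival_offset * 60,
                         peak_vo2 = cfg$resting_mr, arrival_detected = TRUE)
  sc <- score_night(tr, sun, peak = peak)
  expect_equal(sc$mr_min / sc$mr_ref, 0.5, tolerance = 1e-9)
})

test_that("invalid sun times are rejected by the night simulator", {
  cfg <- sim_config()
  sun <- colony_sun()
  sun$next_sunrise <- sun$sunset - 3600
  expect_error(simulate_mr_night(cfg, TRUE, sun, seed = 1),
               class = "torpr_invalid_arg")
})

test_that("with no metabolic heat the nest relaxes to ambient exponentially", {
  cfg <- sim_config(sensor_noise_sd = 0, quantization = 0)
  times <- five_min_grid(hours = 12)
  amb <- make_trace(times, rep(15, length(times)), "amb", "ambient")
  mr <- tibble::tibble(timestamp = times, vo2 = rep(0, length(times)))
  tr <- simulate_tnest_night(cfg, mr, amb, T0 = 30)
  # discrete-time Newtonian cooling: T - Ta decays by (1 - dt*lambda) per step
  k <- seq_along(times) - 1
  expected <- 15 + (30 - 15) * (1 - 5 * cfg$cooling_lambda)^k
  expect_equal(tr$temp_clean, expected, tolerance = 1e-10)
})

test_that("constant forcing settles at the closed-form equilibrium", {
  cfg <- sim_config(sensor_noise_sd = 0, quantization = 0)
  hours <- ceiling(20 / cfg$cooling_lambda / 60) + 2
  times <- five_min_grid(hours = hours)
  amb <- make_trace(times, rep(18, length(times)), "amb", "ambient")
  mr <- tibble::tibble(timestamp = times, vo2 = rep(4, length(times)))
  tr <- simulate_tnest_night(cfg, mr, amb, T0 = 18)
  eq <- 18 + cfg$nest_warming_gamma * 4 / cfg$cooling_lambda
  settle <- times > times[1] + 20 / cfg$cooling_lambda * 60
  expect_true(all(abs(tr$temp_clean[settle] - eq) < 1e-6))
})

test_that("coarse integration matches a 1-second oracle through a 56% MR step", {
  cfg <- sim_config(sensor_noise_sd = 0, quantization = 0)
  times <- five_min_grid(hours = 8)
  n <- length(times)
  amb_c <- rep(18, n)
  mr <- rep(4, n)
  mr[times >= times[1] + 2 * 3600] <- 4 * (1 - 0.56)
  tr <- simulate_tnest_night(cfg, tibble::tibble(timestamp = times, vo2 = mr),
                             make_trace(times, amb_c, "amb", "ambient"),
                             T0 = 18 + 0.06 * 4 / 0.02)
  oracle <- oracle_integrate(times, amb_c, mr, T0 = 18 + 12,
                             gamma = cfg$nest_warming_gamma,
                             lambda = cfg$cooling_lambda)
  # time at which the elevation falls below the 7 C criterion must agree
  # within one sample
  t_pkg <- which(tr$temp_clean - amb_c < 7)[1]
  t_orc <- which(oracle - amb_c < 7)[1]
  expect_lte(abs(t_pkg - t_orc), 1)
})

test_that("mismatched time bases are rejected", {
  cfg <- sim_config()
  times <- five_min_grid(hours = 2)
  amb <- make_trace(times, rep(18, length(times)), "amb", "ambient")
  mr <- tibble::tibble(timestamp = times + 60, vo2 = rep(4, length(times)))
  expect_error(simulate_tnest_night(cfg, mr, amb, T0 = 18),
               class = "torpr_invalid_arg")
})

test_that("season simulation respects torpor_probability = 0 and n_nests > 0", {
  cfg <- sim_config(n_nests = 2, n_instrumented = 0, torpor_probability = 0,
                    season_end = as.Date("2017-06-04"))
  sim <- simulate_season(cfg)
  expect_equal(sum(sim$truth$torpor), 0L)
  expect_error(simulate_season(sim_config(n_nests = 0)),
               class = "torpr_invalid_arg")
})

test_that("season torpor draws land inside the binomial 99% interval", {
  # 40 nests x 60 nights, p = 0.03: count should fall within the central
  # 99% binomial interval around 72
  cfg <- sim_config(n_nests = 40, n_instrumented = 0,
                    season_start = as.Date("2017-06-01"),
                    season_end = as.Date("2017-07-30"),
                    torpor_probability = 0.03, seed = 2024)
  dates <- seq(cfg$season_start, cfg$season_end, by = "day")
  expect_equal(length(dates), 60L)
  sun <- sun_times(cfg$latitude, cfg$longitude, dates)
  p <- cfg$torpor_probability
  draws <- vapply(seq_len(cfg$n_nests), function(i) {
    torpr:::local_seed(substream_seed(cfg$seed, i, 0L),
                       sum(rbinom(length(dates), 1L, p)))
  }, numeric(1))
  count <- sum(draws)
  lo <- qbinom(0.005, 40 * 60, p)
  hi <- qbinom(0.995, 40 * 60, p)
  expect_gte(count, lo)
  expect_lte(count, hi)
})

test_that("identical seeds give byte-identical season files", {
  cfg <- sim_config(n_nests = 2, n_instrumented = 1,
                    season_end = as.Date("2017-06-03"))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_season(simulate_season(cfg), d1)
  write_season(simulate_season(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("nest temperature never falls materially below ambient", {
  cfg <- sim_config(n_nests = 3, n_instrumented = 0, torpor_probability = 0.3,
                    season_end = as.Date("2017-06-10"), seed = 5)
  sim <- simulate_season(cfg)
  floor_c <- min(sim$ambient$temp_c) - 3 * cfg$sensor_noise_sd
  expect_gte(min(sim$nest_temp$temp_c), floor_c)
})

test_that("simulated day records carry the generative group means", {
  days <- simulate_day_records(n_torpor = 200, n_non = 200, sd_resid = 1,
                               seed = 9)
  expect_equal(nrow(days), 400L)
  expect_lt(abs(mean(days$mean_ta[days$torpor]) - 17.3), 0.3)
  expect_lt(abs(mean(days$mean_ta[!days$torpor]) - 20.8), 0.3)
  expect_true(all(days$min_ta < days$mean_ta & days$mean_ta < days$max_ta))
})
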