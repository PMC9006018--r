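# Synthetic colony data: diel ambient forcing, whole-nest metabolic-rate
# profiles (arrival peak, torpor entry/plateau/arousal), and a Newtonian
# nest thermal model, all reproducible from one root seed.

#' Simulate the ambient temperature series at the colony
#'
#' A diel sinusoid (minimum near sunrise, maximum mid-afternoon) plus
#' day-to-day mean shifts drawn from a warm/cold mixture plus Gaussian
#' sample noise. The per-day offsets are attached as attribute
#' `day_offsets` (tibble `date`, `offset`) so downstream code can weight
#' torpor probability by day coolness.
#'
#' @param config A [sim_config()].
#' @param n_days Number of days to simulate (>= 1).
#' @param seed Seed for this trace; defaults to a substream of the config
#'   root seed.
#' @return A tibble with `timestamp` (POSIXct UTC, `sample_interval`
#'   spacing starting at local midnight of `season_start`), `temp_c`,
#'   `source_id = "ambient"`, `role = "ambient"`.
#' @export
#' @examples
#' amb <- simulate_ambient(sim_config(), n_days = 2, seed = 1)
#' range(amb$temp_c)
simulate_ambient <- function(config, n_days,
                             seed = substream_seed(config$seed, 0L, 1L)) {
  cfg <- validate_sim_config(config)
  if (!is.numeric(n_days) || length(n_days) != 1L || is.na(n_days) || n_days < 1) {
    stop_invalid("`n_days` must be a positive count.")
  }
  n_days <- as.integer(n_days)
  start <- as.POSIXct(paste(cfg$season_start, "00:00:00"), tz = "UTC") -
    cfg$timezone_offset * 3600 # local midnight expressed in UTC
  n <- n_days * as.integer(1440 / cfg$sample_interval)
  times <- start + (seq_len(n) - 1L) * cfg$sample_interval * 60
  elapsed_h <- (as.numeric(times) - as.numeric(start)) / 3600
  local_h <- elapsed_h %% 24

  local_seed(seed, {
    cold <- runif(n_days) < cfg$cold_day_prob
    offs <- rnorm(n_days, mean = ifelse(cold, cfg$cold_day_shift, 0),
                  sd = cfg$day_offset_sd)
    noise <- rnorm(n, sd = cfg$ambient_noise_sd)
  })

  # day-mean offsets anchored at local noon and linearly interpolated, so a
  # cold front arrives over hours rather than as a midnight step
  off_t <- if (n_days > 1L) {
    stats::approx(x = (seq_len(n_days) - 1) * 24 + 12, y = offs,
                  xout = elapsed_h, rule = 2)$y
  } else rep(offs, n)
  temp <- cfg$ambient_mean + off_t +
    cfg$ambient_amplitude * cos(2 * pi * (local_h - 17) / 24) + noise
  out <- tibble::tibble(
    timestamp = times, temp_c = temp,
    source_id = "ambient", role = "ambient"
  )
  attr(out, "day_offsets") <- tibble::tibble(
    date = cfg$season_start + seq_len(n_days) - 1L, offset = offs
  )
  out
}

# Noise-free whole-nest VO2 (ml O2/min) at arbitrary instants for the night
# attributed to `sunset`..`sunrise`. Daytime the nestlings alone hold the
# nest at day_mr_fraction * resting; the adults' arrival (arrival_offset
# relative to sunset) adds a decaying spike; on torpor nights an exponential
# entry ramp starts entry_delay after sunset and an arousal ramp completes
# (five time constants) arousal_lead before sunrise.
night_mr_profile <- function(times, sunset, sunrise, torpor, cfg,
                             torpid_fraction = cfg$torpid_fraction) {
  if (is.na(sunset) || is.na(sunrise) || sunrise <= sunset) {
    stop_invalid("Invalid sun times: sunrise must fall after sunset for the night.")
  }
  rest <- cfg$resting_mr
  day <- cfg$day_mr_fraction * rest
  t <- as.numeric(times)
  arrival <- as.numeric(sunset) + cfg$arrival_offset * 60
  departure <- as.numeric(sunrise)

  decay <- function(dt_min, tau) {
    if (tau <= 0) rep(0, length(dt_min)) else exp(-dt_min / tau)
  }

  present <- t >= arrival & t < departure
  v <- ifelse(present, rest, day)
  spike <- (cfg$arrival_peak_height - 1) * rest *
    decay((t - arrival) / 60, cfg$arrival_decay_tau)
  v <- v + ifelse(present, spike, 0)

  if (isTRUE(torpor)) {
    torpid <- rest * (1 - torpid_fraction)
    entry <- as.numeric(sunset) + cfg$entry_delay * 60
    onset <- departure - (cfg$arousal_lead + 5 * cfg$arousal_tau) * 60
    if (onset <= entry) {
      stop_invalid("Night too short for the configured torpor entry/arousal phases.")
    }
    in_entry <- present & t >= entry & t < onset
    in_arousal <- present & t >= onset
    traj_entry <- torpid + (rest - torpid) * decay((t - entry) / 60, cfg$entry_tau)
    v_onset <- torpid + (rest - torpid) *
      decay((onset - entry) / 60, cfg$entry_tau)[1]
    traj_arousal <- rest - (rest - v_onset) * decay((t - onset) / 60, cfg$arousal_tau)
    v <- v + ifelse(in_entry, traj_entry - rest,
                    ifelse(in_arousal, pmin(traj_arousal, rest) - rest, 0))
  }
  v
}

#' Simulate one night's whole-nest gas-exchange trace
#'
#' Produces a VO2/VCO2 trace spanning three hours before sunset to one hour
#' after sunrise at `gas_interval` spacing, together with the ground truth
#' for that night: the generative torpor flag, the noise-free reduction
#' percentage (reference value taken at the arrival peak + 30 min, minimum
#' over the rest of the night, matching the analysis definitions), and the
#' generative entry and arousal-onset instants.
#'
#' @param config A [sim_config()].
#' @param torpor Logical: does the nest enter torpor this night?
#' @param sun One row of a [sun_times()] tibble (needs `date`, `sunset`,
#'   `next_sunrise`).
#' @param seed Seed for the trace noise.
#' @param nest_id Identifier stamped on the trace.
#' @param torpid_fraction Generative depth for this night (defaults to the
#'   config value).
#' @return A list with `trace` (tibble `timestamp`, `vo2`, `vco2`,
#'   `nest_id`, `night_date`) and `truth` (one-row tibble: `nest_id`,
#'   `night_date`, `torpor`, `true_reduction_pct`, `true_entry_time`,
#'   `true_arousal_onset`, `true_peak_time`, `occupants_present`).
#' @export
#' @examples
#' sun <- sun_times(51.0411, 7.8267, as.Date("2017-07-01"))
#' night <- simulate_mr_night(sim_config(), torpor = TRUE, sun = sun, seed = 7)
#' night$truth$true_reduction_pct
simulate_mr_night <- function(config, torpor, sun,
                              seed = config$seed, nest_id = "sim",
                              torpid_fraction = config$torpid_fraction) {
  cfg <- validate_sim_config(config)
  if (!is_flag(torpor)) stop_invalid("`torpor` must be TRUE or FALSE.")
  sunset <- sun$sunset[1]
  sunrise <- sun$next_sunrise[1]
  if (is.na(sunset) || is.na(sunrise) || sunrise <= sunset) {
    stop_invalid("Invalid sun times: next_sunrise must fall after sunset.")
  }
  step <- cfg$gas_interval * 60
  times <- seq(from = sunset - 180 * 60, to = sunrise + 60 * 60, by = step)
  prof <- night_mr_profile(times, sunset, sunrise, torpor, cfg, torpid_fraction)
  local_seed(seed, {
    e1 <- rnorm(length(times), sd = cfg$mr_noise_sd)
    e2 <- rnorm(length(times), sd = cfg$mr_noise_sd * cfg$rer)
  })
  trace <- tibble::tibble(
    timestamp = times,
    vo2 = pmax(prof + e1, 0),
    vco2 = pmax(cfg$rer * prof + e2, 0),
    nest_id = nest_id,
    night_date = sun$date[1]
  )

  list(trace = trace,
       truth = night_truth(cfg, torpor, sun, nest_id, torpid_fraction,
                           times = times, prof = prof))
}

# Ground truth for one nest-night: the noise-free reduction percentage
# (reference at arrival peak + 30 min, minimum over the rest of the night,
# the same definitions the analysis applies) and the generative phase times.
night_truth <- function(cfg, torpor, sun, nest_id,
                        torpid_fraction = cfg$torpid_fraction,
                        times = NULL, prof = NULL) {
  sunset <- sun$sunset[1]
  sunrise <- sun$next_sunrise[1]
  arrival <- sunset + cfg$arrival_offset * 60
  ref_time <- arrival + 30 * 60
  if (torpor) {
    if (is.null(times)) {
      times <- seq(from = sunset - 180 * 60, to = sunrise + 60 * 60,
                   by = cfg$gas_interval * 60)
      prof <- night_mr_profile(times, sunset, sunrise, torpor, cfg,
                               torpid_fraction)
    }
    ref0 <- night_mr_profile(ref_time, sunset, sunrise, torpor, cfg,
                             torpid_fraction)
    win <- times > ref_time & times <= sunrise
    true_red <- (ref0 - min(prof[win])) * 100 / ref0
    entry <- sunset + cfg$entry_delay * 60
    onset <- sunrise - (cfg$arousal_lead + 5 * cfg$arousal_tau) * 60
  } else {
    true_red <- 0
    entry <- as.POSIXct(NA, tz = "UTC")
    onset <- as.POSIXct(NA, tz = "UTC")
  }
  tibble::tibble(
    nest_id = nest_id, night_date = sun$date[1], torpor = torpor,
    true_reduction_pct = true_red,
    true_entry_time = entry, true_arousal_onset = onset,
    true_peak_time = arrival,
    occupants_present = cfg$n_adults + cfg$n_nestlings
  )
}

# First-order heat balance on a regular grid:
#   T[k+1] = T[k] + dt * (-lambda (T[k] - Ta[k]) + gamma MR[k])
# Implemented as a linear recurrence via stats::filter (exact, fast).
integrate_nest_temp <- function(times, ta, mr, T0, gamma, lambda) {
  n <- length(times)
  stopifnot(length(ta) == n, length(mr) == n, n >= 2L)
  dts <- diff(as.numeric(times)) / 60
  dt <- dts[1]
  if (any(abs(dts - dt) > 1e-6)) {
    stop_invalid("Temperature integration requires a uniform time grid.")
  }
  if (dt * lambda >= 1) {
    stop_invalid("Unstable integration: sample_interval * cooling_lambda must be < 1.")
  }
  a <- 1 - dt * lambda
  b <- dt * (lambda * ta[-n] + gamma * mr[-n])
  c(T0, as.numeric(stats::filter(b, a, method = "recursive", init = T0)))
}

#' Simulate a nest-temperature trace from metabolic and ambient forcing
#'
#' Integrates the nest heat balance
#' `T[k+1] = T[k] + dt * (-lambda (T[k] - Ta[k]) + gamma MR[k])` from `T0`,
#' then applies logger-style sensor noise and quantization (0.0625 C grid by
#' default). For constant forcing the fixed point is
#' `Ta + gamma * MR / lambda`.
#'
#' @param config A [sim_config()].
#' @param mr_trace Tibble with `timestamp` and `vo2` (noise-free or noisy
#'   metabolic forcing).
#' @param ambient Tibble with `timestamp` and `temp_c` on the same grid.
#' @param T0 Initial nest temperature, degrees C.
#' @param seed Seed for sensor noise.
#' @param nest_id Identifier stamped on the trace.
#' @return Tibble `timestamp`, `temp_c` (noisy, quantized), `temp_clean`
#'   (integration output), `source_id`, `role = "nest"`.
#' @export
simulate_tnest_night <- function(config, mr_trace, ambient, T0,
                                 seed = config$seed, nest_id = "sim") {
  cfg <- validate_sim_config(config)
  if (nrow(mr_trace) != nrow(ambient) ||
      any(as.numeric(mr_trace$timestamp) != as.numeric(ambient$timestamp))) {
    stop_invalid("`mr_trace` and `ambient` must share one time base.")
  }
  clean <- integrate_nest_temp(mr_trace$timestamp, ambient$temp_c,
                               mr_trace$vo2, T0,
                               cfg$nest_warming_gamma, cfg$cooling_lambda)
  local_seed(seed, {
    noise <- rnorm(length(clean), sd = cfg$sensor_noise_sd)
  })
  q <- cfg$quantization
  noisy <- if (q > 0) round((clean + noise) / q) * q else clean + noise
  tibble::tibble(
    timestamp = mr_trace$timestamp, temp_c = noisy, temp_clean = clean,
    source_id = nest_id, role = "nest"
  )
}

#' Simulate a full monitored breeding season
#'
#' Generates, from one root seed: the colony ambient series; per-nest
#' continuous nest-temperature series driven by the occupants' metabolic
#' profile (nestlings by day, whole family at night, torpor on randomly
#' drawn nights); gas-exchange traces for the instrumented subset of nests;
#' and the ground-truth manifest. Torpor is drawn per nest-night with
#' probability `torpor_probability`, optionally inflated on cold days via a
#' logistic link with slope `ta_coupling_slope` on the day-mean ambient
#' offset. Every nest-night uses a documented substream of the root seed,
#' so single nights are reproducible in isolation.
#'
#' @param config A [sim_config()].
#' @return A list of class `torpr_season`: `config`, `sun` (per-night sun
#'   times), `ambient`, `nest_temp` (all nests, long format), `gas`
#'   (instrumented nests), `truth` (ground-truth manifest: one row per
#'   nest-night).
#' @export
#' @examples
#' sim <- simulate_season(sim_config(n_nests = 2, n_instrumented = 1,
#'                                   season_end = as.Date("2017-06-05")))
#' dplyr::count(sim$truth, torpor)
simulate_season <- function(config) {
  cfg <- validate_sim_config(config)
  if (cfg$n_nests == 0L) stop_invalid("`n_nests` must be at least 1.")
  dates <- seq(cfg$season_start, cfg$season_end, by = "day")
  n_nights <- length(dates)
  sun <- sun_times(cfg$latitude, cfg$longitude, dates)

  ambient <- simulate_ambient(cfg, n_days = n_nights + 2L,
                              seed = substream_seed(cfg$seed, 0L, 1L))
  offsets <- attr(ambient, "day_offsets")
  off_night <- offsets$offset[match(dates, offsets$date)]

  p0 <- cfg$torpor_probability
  p_night <- if (p0 <= 0) rep(0, n_nights) else if (p0 >= 1) rep(1, n_nights) else
    plogis(qlogis(p0) - cfg$ta_coupling_slope * off_night)

  occupied <- local_seed(substream_seed(cfg$seed, 0L, 2L),
                         runif(cfg$n_nests) <= cfg$occupied_fraction)

  times <- ambient$timestamp
  noon_num <- as.numeric(sun$solar_noon)
  slice_idx <- findInterval(as.numeric(times), noon_num)

  nest_ids <- sprintf("nest%03d", seq_len(cfg$n_nests))
  gamma <- cfg$nest_warming_gamma
  lambda <- cfg$cooling_lambda

  sim_one_nest <- function(i) {
    id <- nest_ids[i]
    if (!occupied[i]) {
      torpor <- rep(FALSE, n_nights)
      mr <- rep(0, length(times))
    } else {
      torpor <- local_seed(substream_seed(cfg$seed, i, 0L),
                           rbinom(n_nights, 1L, p_night) == 1L)
      mr <- rep(cfg$day_mr_fraction * cfg$resting_mr, length(times))
      for (j in seq_len(n_nights)) {
        sel <- slice_idx == j
        if (!any(sel)) next
        mr[sel] <- night_mr_profile(times[sel], sun$sunset[j],
                                    sun$next_sunrise[j], torpor[j], cfg)
      }
      mr[slice_idx == 0L] <- cfg$day_mr_fraction * cfg$resting_mr
    }
    T0 <- ambient$temp_c[1] + gamma * mr[1] / lambda
    nest_trace <- simulate_tnest_night(
      cfg,
      tibble::tibble(timestamp = times, vo2 = mr),
      ambient, T0,
      seed = substream_seed(cfg$seed, i, 1L), nest_id = id
    )
    nest_trace$nest_id <- id

    gas <- NULL
    truth <- NULL
    if (occupied[i]) {
      if (i <= cfg$n_instrumented) {
        nights_out <- purrr::map(seq_len(n_nights), function(j) {
          simulate_mr_night(cfg, torpor[j], sun[j, ],
                            seed = substream_seed(cfg$seed, i, 100L + j),
                            nest_id = id)
        })
        truth <- dplyr::bind_rows(purrr::map(nights_out, "truth"))
        gas <- dplyr::bind_rows(purrr::map(nights_out, "trace"))
      } else {
        truth <- dplyr::bind_rows(purrr::map(seq_len(n_nights), function(j) {
          night_truth(cfg, torpor[j], sun[j, ], nest_id = id)
        }))
      }
    } else {
      truth <- tibble::tibble(
        nest_id = id, night_date = dates, torpor = FALSE,
        true_reduction_pct = 0,
        true_entry_time = as.POSIXct(NA, tz = "UTC"),
        true_arousal_onset = as.POSIXct(NA, tz = "UTC"),
        true_peak_time = as.POSIXct(NA, tz = "UTC"),
        occupants_present = 0L
      )
    }
    truth$occupied <- occupied[i]
    list(nest_temp = nest_trace, gas = gas, truth = truth)
  }

  parts <- purrr::map(seq_len(cfg$n_nests), sim_one_nest)
  structure(list(
    config = cfg,
    sun = sun,
    ambient = ambient,
    nest_temp = dplyr::bind_rows(purrr::map(parts, "nest_temp")),
    gas = dplyr::bind_rows(purrr::compact(purrr::map(parts, "gas"))),
    truth = dplyr::bind_rows(purrr::map(parts, "truth"))
  ), class = "torpr_season")
}

#' @export
print.torpr_season <- function(x, ...) {
  cat("<torpr_season>\n")
  cat(sprintf("  %d nests x %d nights (%s .. %s), %d torpor nights\n",
              x$config$n_nests, nrow(x$sun),
              x$config$season_start, x$config$season_end,
              sum(x$truth$torpor)))
  cat(sprintf("  temperature rows: %d nest, %d ambient; gas rows: %d\n",
              nrow(x$nest_temp), nrow(x$ambient), nrow(x$gas)))
  invisible(x)
}

#' Simulate one coupled nest-night (gas trace + nest and ambient temperature)
#'
#' Convenience wrapper producing everything the two-signal analysis of a
#' single night needs: the noisy gas-exchange trace (1-min grid), a
#' diel-sinusoid ambient trace and the thermally coupled nest-temperature
#' trace (both on the `sample_interval` grid), and the night's ground
#' truth. The nest integrates the *noise-free* metabolic profile: sensor
#' noise belongs to the loggers, not to the heat balance.
#'
#' @inheritParams simulate_mr_night
#' @return A list: `gas`, `nest`, `ambient`, `truth`, `sun`.
#' @export
#' @examples
#' sun <- sun_times(51.0411, 7.8267, as.Date("2017-07-01"))
#' night <- simulate_nest_night(sim_config(), torpor = TRUE, sun = sun, seed = 2)
#' names(night)
simulate_nest_night <- function(config, torpor, sun,
                                seed = config$seed, nest_id = "sim",
                                torpid_fraction = config$torpid_fraction) {
  cfg <- validate_sim_config(config)
  mr <- simulate_mr_night(cfg, torpor, sun, seed = seed, nest_id = nest_id,
                          torpid_fraction = torpid_fraction)
  t_lo <- min(mr$trace$timestamp)
  t_hi <- max(mr$trace$timestamp)
  times5 <- seq(t_lo, t_hi, by = cfg$sample_interval * 60)
  local_h <- ((as.numeric(times5) / 3600 + cfg$timezone_offset)) %% 24
  amb_noise <- local_seed(substream_seed(seed, 1L, 7L),
                          rnorm(length(times5), sd = cfg$ambient_noise_sd))
  ambient <- tibble::tibble(
    timestamp = times5,
    temp_c = cfg$ambient_mean +
      cfg$ambient_amplitude * cos(2 * pi * (local_h - 17) / 24) + amb_noise,
    source_id = "ambient", role = "ambient"
  )
  prof5 <- night_mr_profile(times5, sun$sunset[1], sun$next_sunrise[1],
                            torpor, cfg, torpid_fraction)
  T0 <- ambient$temp_c[1] +
    cfg$nest_warming_gamma * prof5[1] / cfg$cooling_lambda
  nest <- simulate_tnest_night(
    cfg, tibble::tibble(timestamp = times5, vo2 = prof5), ambient, T0,
    seed = substream_seed(seed, 1L, 8L), nest_id = nest_id
  )
  list(gas = mr$trace, nest = nest, ambient = ambient, truth = mr$truth,
       sun = sun)
}

#' Simulate day-level ambient records for the torpor-day contrast
#'
#' Generates one row per measurement day with daily mean/min/max ambient
#' temperature and the torpor status of the *following* night, the layout
#' [contrast_ambient()] consumes. Group means are generative settings;
#' year- and nest-level random intercepts default to zero SD.
#'
#' @param n_torpor,n_non Number of days preceding torpor and non-torpor
#'   nights.
#' @param mean_torpor,mean_non Generative day-mean ambient temperature (C)
#'   for the two groups.
#' @param sd_resid Residual SD of the day means, degrees C.
#' @param sd_year,sd_nest SDs of year and nest random intercepts.
#' @param n_years,n_nests Number of year and nest levels, assigned cyclically.
#' @param seed Seed.
#' @return Tibble `day_id`, `year`, `nest_id`, `torpor`, `mean_ta`,
#'   `min_ta`, `max_ta`.
#' @export
simulate_day_records <- function(n_torpor = 6L, n_non = 54L,
                                 mean_torpor = 17.3, mean_non = 20.8,
                                 sd_resid = 2.9, sd_year = 0, sd_nest = 0,
                                 n_years = 2L, n_nests = 2L, seed = 1L) {
  n <- n_torpor + n_non
  if (n_torpor < 1L || n_non < 1L) stop_invalid("Both groups must be non-empty.")
  torpor <- c(rep(TRUE, n_torpor), rep(FALSE, n_non))
  year <- rep_len(paste0("y", seq_len(n_years)), n)
  nest <- rep_len(sprintf("nest%02d", seq_len(n_nests)), n)
  local_seed(seed, {
    ye <- rnorm(n_years, sd = sd_year)
    ne <- rnorm(n_nests, sd = sd_nest)
    resid <- rnorm(n, sd = sd_resid)
    spread_lo <- abs(rnorm(n, 1.5, 0.3))
    spread_hi <- abs(rnorm(n, 2.0, 0.3))
  })
  mu <- ifelse(torpor, mean_torpor, mean_non)
  mean_ta <- mu + ye[match(year, unique(year))] + ne[match(nest, unique(nest))] + resid
  tibble::tibble(
    day_id = sprintf("d%03d", seq_len(n)),
    year = year, nest_id = nest, torpor = torpor,
    mean_ta = mean_ta,
    min_ta = mean_ta - spread_lo,
    max_ta = mean_ta + spread_hi
  )
}
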