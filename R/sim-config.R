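#' Simulation configuration for synthetic colony data
#'
#' Bundles every parameter of the synthetic-data generator. Defaults describe
#' a mid-latitude colony (the bridge site at 51.04 N, 7.83 E) monitored over
#' a summer breeding season (a thermally massive enclosure, hence a damped
#' diel ambient cycle), with magnitudes chosen so that the generated
#' physiology matches the field study the detectors target: whole-nest
#' resting oxygen consumption of 4 ml O2 min^-1, an occupied-nest thermal
#' elevation of gamma * MR / lambda = 12 C at night (9 C by day, when only
#' the nestlings are present), torpor depth 56% of the resting rate, entry
#' starting 19 min after sunset and arousal completing 45 min before sunrise.
#'
#' @param latitude,longitude Site coordinates, decimal degrees.
#' @param timezone_offset Civil offset from UTC in hours (used for night/day
#'   attribution of timestamps; all stored instants are UTC).
#' @param season_start,season_end First and last night (calendar date of the
#'   sunset) of the simulated season.
#' @param n_nests Number of occupied-nest series to simulate.
#' @param n_instrumented Number of nests that also get gas-exchange traces
#'   (respirometry nest-boxes); capped at `n_nests`.
#' @param occupied_fraction Fraction of nests occupied; unoccupied nests emit
#'   no heat and serve as negative controls for occupancy inference.
#' @param sample_interval Temperature sampling interval, minutes.
#' @param gas_interval Gas-trace sampling interval, minutes.
#' @param ambient_mean,ambient_amplitude Mean and semi-amplitude of the diel
#'   ambient sinusoid, degrees C (minimum near sunrise, maximum
#'   mid-afternoon).
#' @param ambient_noise_sd Gaussian measurement/turbulence noise on ambient
#'   samples, degrees C.
#' @param cold_day_prob,cold_day_shift,day_offset_sd Day-to-day mean shifts:
#'   each day's offset is drawn from a two-component mixture, a "warm"
#'   component N(0, `day_offset_sd`) and with probability `cold_day_prob` a
#'   "cold" component N(`cold_day_shift`, `day_offset_sd`), so the season
#'   contains distinct cold spells.
#' @param nest_warming_gamma Heat-input coefficient, degrees C per
#'   (ml O2 min^-1) per minute: converts whole-nest metabolic rate into
#'   nest-wall warming rate.
#' @param cooling_lambda Newtonian cooling rate of the nest wall towards
#'   ambient, per minute (thermal time constant = 1 / `cooling_lambda`).
#' @param resting_mr Whole-nest resting oxygen consumption at night (all
#'   occupants present), ml O2 min^-1.
#' @param day_mr_fraction Daytime whole-nest metabolic rate as a fraction of
#'   `resting_mr` (nestlings stay in the nest while adults forage).
#' @param torpid_fraction Generative torpor depth: metabolic rate during the
#'   torpor plateau is `resting_mr * (1 - torpid_fraction)`. In `[0, 1]`.
#' @param torpor_probability Baseline per-nest-night probability of torpor.
#' @param ta_coupling_slope Logistic slope (per degree C) coupling torpor
#'   probability to the day-mean ambient offset; colder days raise the
#'   probability. 0 disables the coupling.
#' @param entry_delay Minutes after sunset at which the metabolic decline
#'   starts on torpor nights.
#' @param entry_tau,arousal_tau Time constants (minutes) of the exponential
#'   entry decline and arousal rewarming ramps. A ramp is considered
#'   complete after five time constants.
#' @param arousal_lead Minutes before sunrise at which the arousal ramp
#'   completes.
#' @param arrival_offset Minutes relative to sunset at which the adults
#'   arrive (negative = before sunset).
#' @param arrival_peak_height Arrival spike height as a multiple of
#'   `resting_mr`.
#' @param arrival_decay_tau Decay time constant of the arrival spike,
#'   minutes (the spike relaxes to the resting plateau well within 30 min).
#' @param mr_noise_sd Additive Gaussian noise on gas traces, same units as
#'   `resting_mr`.
#' @param rer Respiratory exchange ratio used to derive VCO2 from VO2.
#' @param sensor_noise_sd Temperature-logger accuracy noise SD, degrees C.
#' @param quantization Logger resolution, degrees C (values are snapped to
#'   this grid, emulating 0.0625 C logger steps).
#' @param n_adults,n_nestlings Occupants per occupied nest.
#' @param seed Root seed; every nest-night derives a documented substream
#'   seed from it (see [substream_seed()]).
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_nests = 4)
#' cfg$torpid_fraction
sim_config <- function(latitude = 51.0411,
                       longitude = 7.8267,
                       timezone_offset = 2,
                       season_start = as.Date("2017-06-01"),
                       season_end = as.Date("2017-07-31"),
                       n_nests = 40L,
                       n_instrumented = 3L,
                       occupied_fraction = 1,
                       sample_interval = 5,
                       gas_interval = 1,
                       ambient_mean = 18,
                       ambient_amplitude = 1.5,
                       ambient_noise_sd = 0.3,
                       cold_day_prob = 0.2,
                       cold_day_shift = -6,
                       day_offset_sd = 1.5,
                       nest_warming_gamma = 0.06,
                       cooling_lambda = 0.02,
                       resting_mr = 4,
                       day_mr_fraction = 0.75,
                       torpid_fraction = 0.56,
                       torpor_probability = 0.03,
                       ta_coupling_slope = 0,
                       entry_delay = 19,
                       entry_tau = 30,
                       arousal_tau = 20,
                       arousal_lead = 45,
                       arrival_offset = -20,
                       arrival_peak_height = 2,
                       arrival_decay_tau = 6,
                       mr_noise_sd = 0.2,
                       rer = 0.85,
                       sensor_noise_sd = 0.2,
                       quantization = 0.0625,
                       n_adults = 2L,
                       n_nestlings = 2L,
                       seed = 1L) {
  cfg <- list(
    latitude = latitude, longitude = longitude,
    timezone_offset = timezone_offset,
    season_start = as.Date(season_start), season_end = as.Date(season_end),
    n_nests = as.integer(n_nests), n_instrumented = as.integer(n_instrumented),
    occupied_fraction = occupied_fraction,
    sample_interval = sample_interval, gas_interval = gas_interval,
    ambient_mean = ambient_mean, ambient_amplitude = ambient_amplitude,
    ambient_noise_sd = ambient_noise_sd,
    cold_day_prob = cold_day_prob, cold_day_shift = cold_day_shift,
    day_offset_sd = day_offset_sd,
    nest_warming_gamma = nest_warming_gamma, cooling_lambda = cooling_lambda,
    resting_mr = resting_mr, day_mr_fraction = day_mr_fraction,
    torpid_fraction = torpid_fraction,
    torpor_probability = torpor_probability,
    ta_coupling_slope = ta_coupling_slope,
    entry_delay = entry_delay, entry_tau = entry_tau,
    arousal_tau = arousal_tau, arousal_lead = arousal_lead,
    arrival_offset = arrival_offset,
    arrival_peak_height = arrival_peak_height,
    arrival_decay_tau = arrival_decay_tau,
    mr_noise_sd = mr_noise_sd, rer = rer,
    sensor_noise_sd = sensor_noise_sd, quantization = quantization,
    n_adults = as.integer(n_adults), n_nestlings = as.integer(n_nestlings),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#'
#' @param cfg A `sim_config` object (or plain named list with its fields).
#' @return The validated config, invisibly classed as `sim_config`.
#' @export
validate_sim_config <- function(cfg) {
  check_number(cfg$latitude, "latitude", -90, 90)
  check_number(cfg$longitude, "longitude", -180, 180)
  check_number(cfg$torpid_fraction, "torpid_fraction", 0, 1)
  check_number(cfg$torpor_probability, "torpor_probability", 0, 1)
  check_number(cfg$occupied_fraction, "occupied_fraction", 0, 1)
  check_number(cfg$day_mr_fraction, "day_mr_fraction", 0, 1)
  if (cfg$sample_interval <= 0 || cfg$gas_interval <= 0) {
    stop_invalid("Sampling intervals must be positive.")
  }
  if (cfg$cooling_lambda <= 0) stop_invalid("`cooling_lambda` must be > 0.")
  if (cfg$nest_warming_gamma < 0) stop_invalid("`nest_warming_gamma` must be >= 0.")
  for (f in c("entry_tau", "arousal_tau", "arrival_decay_tau")) {
    if (cfg[[f]] < 0) stop_invalid(paste0("`", f, "` must be >= 0."))
  }
  for (f in c("ambient_noise_sd", "mr_noise_sd", "sensor_noise_sd",
              "quantization", "resting_mr", "arousal_lead")) {
    if (cfg[[f]] < 0) stop_invalid(paste0("`", f, "` must be >= 0."))
  }
  if (cfg$n_nests < 0L) stop_invalid("`n_nests` must be >= 0.")
  if (cfg$season_end < cfg$season_start) {
    stop_invalid("`season_end` must not precede `season_start`.")
  }
  cfg$n_instrumented <- min(cfg$n_instrumented, cfg$n_nests)
  class(cfg) <- "sim_config"
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  site: %.4f N, %.4f E (UTC%+g)\n",
              x$latitude, x$longitude, x$timezone_offset))
  cat(sprintf("  season: %s .. %s, %d nests (%d instrumented)\n",
              x$season_start, x$season_end, x$n_nests, x$n_instrumented))
  cat(sprintf("  thermal: gamma=%g, lambda=%g (night elevation %.1f C)\n",
              x$nest_warming_gamma, x$cooling_lambda,
              x$nest_warming_gamma * x$resting_mr / x$cooling_lambda))
  cat(sprintf("  torpor: depth %.0f%%, p=%g per nest-night, seed %d\n",
              100 * x$torpid_fraction, x$torpor_probability, x$seed))
  invisible(x)
}

#' Write / read a simulation configuration as YAML
#'
#' @param cfg A `sim_config`.
#' @param path File path.
#' @return `write_sim_config()` returns `path` invisibly; `read_sim_config()`
#'   returns a validated `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$season_start <- as.character(x$season_start)
  x$season_end <- as.character(x$season_end)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$season_start <- as.Date(x$season_start)
  x$season_end <- as.Date(x$season_end)
  cfg <- do.call(sim_config, x)
  cfg
}
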