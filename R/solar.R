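# Sunset/sunrise computation (NOAA spreadsheet algorithm, Julian-century
# form). Nocturnal statistics throughout the package are referenced to these
# events: "night" is the half-open interval [sunset, next sunrise).

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Core NOAA solar quantities for a date (computed at local solar noonish).
# Returns equation of time (minutes) and solar declination (degrees).
noaa_eqtime_decl <- function(date) {
  jd <- as.numeric(date) + 2440587.5 + 0.5 # JD at 12:00 UT of the civil date
  jc <- (jd - 2451545) / 36525
  gml <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  gma <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  eqctr <- sin(deg2rad(gma)) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(deg2rad(2 * gma)) * (0.019993 - 0.000101 * jc) +
    sin(deg2rad(3 * gma)) * 0.000289
  true_long <- gml + eqctr
  app_long <- true_long - 0.00569 - 0.00478 * sin(deg2rad(125.04 - 1934.136 * jc))
  mean_obliq <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  obliq <- mean_obliq + 0.00256 * cos(deg2rad(125.04 - 1934.136 * jc))
  decl <- rad2deg(asin(sin(deg2rad(obliq)) * sin(deg2rad(app_long))))
  var_y <- tan(deg2rad(obliq / 2))^2
  eqtime <- 4 * rad2deg(
    var_y * sin(2 * deg2rad(gml)) -
      2 * ecc * sin(deg2rad(gma)) +
      4 * ecc * var_y * sin(deg2rad(gma)) * cos(2 * deg2rad(gml)) -
      0.5 * var_y^2 * sin(4 * deg2rad(gml)) -
      1.25 * ecc^2 * sin(2 * deg2rad(gma))
  )
  list(eqtime = eqtime, decl = decl)
}

#' Sunset, sunrise and solar noon for a site
#'
#' Computes geometric sunrise/sunset (solar altitude `sun_altitude`, default
#' -0.833 degrees: the standard almanac convention including atmospheric
#' refraction and the solar radius) and solar noon with the NOAA solar
#' position algorithm. All returned instants are POSIXct in UTC;
#' `timezone_offset` only affects none of the instants, it is accepted so
#' call sites can carry the site convention alongside.
#'
#' `next_sunrise` is the sunrise of the following civil date, so
#' `[sunset, next_sunrise)` is the night attributed to `date`.
#'
#' @param latitude,longitude Site coordinates in decimal degrees
#'   (north/east positive). `abs(latitude)` must be below 66.5: polar
#'   day/night is not handled.
#' @param dates Date vector (or coercible) of civil dates.
#' @param sun_altitude Solar altitude in degrees defining rise/set.
#' @return A tibble with one row per date: `date`, `sunrise`, `solar_noon`,
#'   `sunset`, `next_sunrise`, `daylength_h`.
#' @export
#' @examples
#' sun_times(51.0411, 7.8267, as.Date("2017-07-01"))
sun_times <- function(latitude, longitude, dates, sun_altitude = -0.833) {
  check_number(latitude, "latitude", -90, 90)
  check_number(longitude, "longitude", -180, 180)
  if (abs(latitude) >= 66.5) {
    stop_invalid("`latitude` beyond 66.5 degrees: polar day/night is not supported.")
  }
  dates <- as.Date(dates)
  if (length(dates) == 0L) stop_invalid("`dates` must contain at least one date.")

  one_day <- function(d) {
    s <- noaa_eqtime_decl(d)
    zen <- 90 - sun_altitude
    cos_ha <- cos(deg2rad(zen)) / (cos(deg2rad(latitude)) * cos(deg2rad(s$decl))) -
      tan(deg2rad(latitude)) * tan(deg2rad(s$decl))
    if (abs(cos_ha) > 1) {
      stop_invalid("Sun does not cross the requested altitude on this date (polar condition).")
    }
    ha <- rad2deg(acos(cos_ha))
    midnight <- as.POSIXct(paste(d, "00:00:00"), tz = "UTC")
    noon_min <- 720 - 4 * longitude - s$eqtime # minutes UTC
    c(sunrise = noon_min - ha * 4, noon = noon_min, sunset = noon_min + ha * 4,
      midnight = as.numeric(midnight))
  }
  m <- vapply(as.list(c(dates, max(dates) + 1L)), one_day, numeric(4))
  at <- function(col, row) {
    as.POSIXct(m["midnight", col] + 60 * m[row, col],
               origin = "1970-01-01", tz = "UTC")
  }
  idx <- seq_along(dates)
  out <- tibble::tibble(
    date = dates,
    sunrise = at(idx, "sunrise"),
    solar_noon = at(idx, "noon"),
    sunset = at(idx, "sunset"),
    next_sunrise = at(match(dates + 1L, c(dates, max(dates) + 1L)), "sunrise"),
    daylength_h = (m["sunset", idx] - m["sunrise", idx]) / 60
  )
  out
}

#' Night window derived from sun times
#'
#' @param sun A tibble from [sun_times()].
#' @return Tibble with `night_date`, `start` (sunset) and `end`
#'   (next sunrise); the half-open interval `[start, end)` is the night all
#'   nocturnal statistics use.
#' @export
night_window <- function(sun) {
  stopifnot(all(c("date", "sunset", "next_sunrise") %in% names(sun)))
  if (any(sun$next_sunrise <= sun$sunset)) {
    stop_invalid("Invalid sun times: next_sunrise must fall after sunset.")
  }
  tibble::tibble(night_date = sun$date, start = sun$sunset, end = sun$next_sunrise)
}
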