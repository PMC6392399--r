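#' Sunrise and sunset times (NOAA solar position algorithm)
#'
#' Computes apparent sunrise and sunset (solar zenith 90.833 degrees,
#' i.e. including standard refraction and the solar disc radius) for a
#' calendar date at a latitude/longitude, using the NOAA low-accuracy solar
#' position equations (Spencer Fourier series for declination and the
#' equation of time).  Accuracy is well under a minute at mid latitudes,
#' which is the basis for the legal-shooting-time diel rule.
#'
#' @param date A `Date` (or coercible) vector.
#' @param lat Latitude in decimal degrees (north positive).
#' @param lon Longitude in decimal degrees (east positive).
#' @return A data frame with POSIXct columns `sunrise` and `sunset` (UTC).
#'   Errors on polar day/night (no sunrise at that date/latitude).
#' @export
solar_times <- function(date, lat, lon) {
  date <- as.Date(date)
  doy <- as.integer(strftime(date, "%j", tz = "UTC"))
  yl <- ifelse(as.integer(strftime(date, "%Y", tz = "UTC")) %% 4 == 0, 366, 365)
  g <- 2 * pi / yl * (doy - 1 + 0.5)  # fractional year at solar noon, radians
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g)
                      - 0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- (0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g)
           - 0.006758 * cos(2 * g) + 0.000907 * sin(2 * g)
           - 0.002697 * cos(3 * g) + 0.00148 * sin(3 * g))
  phi <- lat * pi / 180
  zen <- 90.833 * pi / 180
  cos_ha <- cos(zen) / (cos(phi) * cos(decl)) - tan(phi) * tan(decl)
  if (any(cos_ha < -1 | cos_ha > 1)) {
    stop("polar day or night: no sunrise/sunset at this date and latitude")
  }
  ha <- acos(cos_ha) * 180 / pi  # degrees
  midnight <- as.POSIXct(paste(format(date), "00:00:00"), tz = "UTC")
  sunrise <- midnight + 60 * (720 - 4 * (lon + ha) - eqtime)
  sunset <- midnight + 60 * (720 - 4 * (lon - ha) - eqtime)
  data.frame(sunrise = sunrise, sunset = sunset)
}

#' Solar elevation angle
#'
#' Apparent-free geometric solar elevation (degrees) at an instant, from the
#' same declination / equation-of-time series as [solar_times()].  Used for
#' cross-checks of the sunrise/sunset inversion.
#'
#' @param time POSIXct (UTC).
#' @param lat,lon Coordinates in decimal degrees.
#' @return Elevation in degrees.
#' @export
solar_elevation <- function(time, lat, lon) {
  date <- as.Date(time, tz = "UTC")
  doy <- as.integer(strftime(time, "%j", tz = "UTC"))
  yl <- ifelse(as.integer(strftime(time, "%Y", tz = "UTC")) %% 4 == 0, 366, 365)
  frac_hour <- (as.numeric(time) -
                as.numeric(as.POSIXct(paste(format(date), "00:00:00"),
                                      tz = "UTC"))) / 3600
  g <- 2 * pi / yl * (doy - 1 + (frac_hour - 12) / 24)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g)
                      - 0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- (0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g)
           - 0.006758 * cos(2 * g) + 0.000907 * sin(2 * g)
           - 0.002697 * cos(3 * g) + 0.00148 * sin(3 * g))
  tst <- frac_hour * 60 + eqtime + 4 * lon  # true solar time, minutes
  ha <- (tst / 4 - 180) * pi / 180
  phi <- lat * pi / 180
  elev <- asin(sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(ha))
  elev * 180 / pi
}
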