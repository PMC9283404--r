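# Solar position: sunrise/sunset from the NOAA spreadsheet equations
# (Julian-century formulation).  Local civil time = UTC + tz_offset; the study
# design assumes a single timezone without DST.

SOLAR_ZENITH_OFFICIAL <- 90.833  # degrees; includes refraction + solar radius

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Julian day at 00:00 UTC for a Date
julian_day <- function(date) as.numeric(as.Date(date)) + 2440587.5

#' Sunrise and sunset for one location and a vector of dates
#'
#' Computes local-civil sunrise/sunset with the NOAA solar equations
#' (equation of time and solar declination from the Julian century, hour
#' angle at zenith 90.833 deg).  Accuracy is within about a minute of the
#' NOAA reference calculator at mid latitudes.
#'
#' @param latitude,longitude decimal degrees (WGS84; east/north positive).
#' @param date `Date` vector.
#' @param tz_offset hours ahead of UTC of local civil time.
#' @return data.frame with `date`, `sunrise`, `sunset` (fractional local
#'   hours), and `polar` (`TRUE` when the sun never rises or never sets, in
#'   which case sunrise/sunset are `NA`).
#' @examples
#' solar_times(38.55, 139.85, as.Date("2019-06-21"), tz_offset = 9)
#' @export
solar_times <- function(latitude, longitude, date, tz_offset) {
  stopifnot(length(latitude) == 1, length(longitude) == 1)
  if (latitude < -90 || latitude > 90 || longitude < -180 || longitude > 180)
    stopf("invalid coordinates (lat %s, lon %s)", latitude, longitude)
  date <- as.Date(date)
  # evaluate the slowly-varying terms at local solar noon
  jd <- julian_day(date) + 0.5 - longitude / 360
  jc <- (jd - 2451545) / 36525

  gml <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  gma <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  ceq <- sin(deg2rad(gma)) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(deg2rad(2 * gma)) * (0.019993 - 0.000101 * jc) +
    sin(deg2rad(3 * gma)) * 0.000289
  tlong <- gml + ceq
  omega <- 125.04 - 1934.136 * jc
  applong <- tlong - 0.00569 - 0.00478 * sin(deg2rad(omega))
  obl0 <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  obl <- obl0 + 0.00256 * cos(deg2rad(omega))
  decl <- asin(sin(deg2rad(obl)) * sin(deg2rad(applong)))

  y <- tan(deg2rad(obl / 2))^2
  eot <- 4 * rad2deg(
    y * sin(2 * deg2rad(gml)) - 2 * ecc * sin(deg2rad(gma)) +
      4 * ecc * y * sin(deg2rad(gma)) * cos(2 * deg2rad(gml)) -
      0.5 * y^2 * sin(4 * deg2rad(gml)) - 1.25 * ecc^2 * sin(2 * deg2rad(gma))
  )

  phi <- deg2rad(latitude)
  cos_ha <- cos(deg2rad(SOLAR_ZENITH_OFFICIAL)) / (cos(phi) * cos(decl)) -
    tan(phi) * tan(decl)
  polar <- abs(cos_ha) > 1
  ha <- rad2deg(acos(pmin(pmax(cos_ha, -1), 1)))

  noon <- 720 - 4 * longitude - eot + 60 * tz_offset   # minutes, local civil
  sunrise <- (noon - 4 * ha) / 60
  sunset <- (noon + 4 * ha) / 60
  sunrise[polar] <- NA_real_
  sunset[polar] <- NA_real_
  data.frame(date = date, sunrise = sunrise, sunset = sunset, polar = polar)
}

#' Solar times for every site and date of a survey
#'
#' Vectorised wrapper around [solar_times()] producing one row per site per
#' date.  An override table, when supplied, takes precedence over the
#' computed values (e.g. to reproduce an analysis done with published
#' almanac times).
#'
#' @param sites site table (see [read_sites()]); one row per site is used
#'   (`site_id`, `latitude`, `longitude`).
#' @param dates `Date` vector of survey days.
#' @param tz_offset hours ahead of UTC.
#' @param overrides optional data.frame `site_id, date, sunrise, sunset` with
#'   `"HH:MM"` times.
#' @return data.frame `site_id, date, sunrise, sunset, polar`; times are
#'   `POSIXct` local civil timestamps on the given date.
#' @export
compute_solar_times <- function(sites, dates, tz_offset, overrides = NULL) {
  usite <- unique(sites[, c("site_id", "latitude", "longitude")])
  dates <- sort(unique(as.Date(dates)))
  out <- do.call(rbind, lapply(seq_len(nrow(usite)), function(i) {
    if (is.na(usite$latitude[i]) || is.na(usite$longitude[i])) {
      # unknown position: rows stay NA unless an override fills them
      st <- data.frame(date = dates, sunrise = NA_real_, sunset = NA_real_,
                       polar = FALSE)
    } else {
      st <- solar_times(usite$latitude[i], usite$longitude[i], dates, tz_offset)
    }
    cbind(site_id = usite$site_id[i], st)
  }))
  if (!is.null(overrides) && nrow(overrides)) {
    ov <- overrides
    ov$date <- as.Date(ov$date)
    key <- paste(out$site_id, out$date)
    okey <- paste(ov$site_id, ov$date)
    hit <- match(key, okey)
    idx <- which(!is.na(hit))
    if (length(idx)) {
      out$sunrise[idx] <- parse_clock(ov$sunrise[hit[idx]])
      out$sunset[idx] <- parse_clock(ov$sunset[hit[idx]])
      out$polar[idx] <- FALSE
    }
  }
  out$sunrise <- make_timestamp(out$date, out$sunrise)
  out$sunset <- make_timestamp(out$date, out$sunset)
  rownames(out) <- NULL
  out
}
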