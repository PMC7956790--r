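# NOAA-style solar position (Meeus approximations as used in the NOAA solar
# calculator spreadsheets): Julian century -> solar declination and equation
# of time -> true solar time via the longitude correction -> hour angle ->
# altitude/azimuth by spherical trigonometry. No atmospheric refraction
# (< 0.05 degrees above 25 degrees altitude, irrelevant at this precision).

parse_timestamp_utc <- function(timestamp) {
  if (inherits(timestamp, "POSIXct"))
    return(as.numeric(timestamp))             # POSIXct is an absolute instant
  m <- regmatches(timestamp, regexec(
    "^(\\d{4})-(\\d{2})-(\\d{2})[T ](\\d{2}):(\\d{2})(?::(\\d{2}(?:\\.\\d+)?))?\\s*(Z|[+-]\\d{2}:?\\d{2})$",
    timestamp))[[1]]
  if (!length(m))
    stop("timestamp must carry an explicit UTC offset, e.g. '2019-06-19T18:54:00+02:00'")
  ymd <- as.numeric(m[2:4]); hms <- as.numeric(m[5:6])
  sec <- if (nzchar(m[7])) as.numeric(m[7]) else 0
  off <- m[8]
  off_min <- if (off == "Z") 0 else {
    sgn <- if (substr(off, 1, 1) == "-") -1 else 1
    hh <- as.numeric(substr(off, 2, 3))
    mm <- as.numeric(sub("^[+-]\\d{2}:?", "", off))
    sgn * (hh * 60 + mm)
  }
  days <- as.numeric(ISOdate(ymd[1], ymd[2], ymd[3], 0, 0, 0, tz = "UTC"))
  days + hms[1] * 3600 + hms[2] * 60 + sec - off_min * 60
}

#' Solar altitude and azimuth for a site and timestamp
#'
#' Computes the apparent solar position with the NOAA calculator algorithm
#' (declination and equation of time from the Julian century, hour angle
#' from true solar time, spherical trigonometry for altitude and azimuth).
#' Refraction is not applied. The timestamp must carry an explicit UTC
#' offset — the local civil zone is never assumed.
#'
#' @param latitude_deg latitude in degrees, north positive, `[-90, 90]`.
#' @param longitude_deg longitude in degrees, east positive, `[-180, 180]`.
#' @param timestamp ISO-8601 string with offset (e.g.
#'   `"2019-06-19T18:54:00+02:00"`) or a `POSIXct`.
#' @return named numeric vector `c(altitude_deg, azimuth_deg)`; azimuth is
#'   clockwise from north in `[0, 360)`.
#' @export
solar_position <- function(latitude_deg, longitude_deg, timestamp) {
  stopifnot(abs(latitude_deg) <= 90, abs(longitude_deg) <= 180)
  unix <- parse_timestamp_utc(timestamp)
  jd <- unix / 86400 + 2440587.5
  T_ <- (jd - 2451545) / 36525
  rad <- pi / 180
  L0 <- (280.46646 + T_ * (36000.76983 + 0.0003032 * T_)) %% 360
  M <- 357.52911 + T_ * (35999.05029 - 0.0001537 * T_)
  e <- 0.016708634 - T_ * (0.000042037 + 0.0000001267 * T_)
  C <- sin(M * rad) * (1.914602 - T_ * (0.004817 + 0.000014 * T_)) +
    sin(2 * M * rad) * (0.019993 - 0.000101 * T_) +
    sin(3 * M * rad) * 0.000289
  true_long <- L0 + C
  omega <- 125.04 - 1934.136 * T_
  lambda <- true_long - 0.00569 - 0.00478 * sin(omega * rad)
  eps0 <- 23 + (26 + (21.448 - T_ * (46.815 + T_ * (0.00059 - 0.001813 * T_))) / 60) / 60
  eps <- eps0 + 0.00256 * cos(omega * rad)
  decl <- asin(sin(eps * rad) * sin(lambda * rad)) / rad
  y <- tan(eps * rad / 2)^2
  eqtime <- 4 / rad * (y * sin(2 * L0 * rad) - 2 * e * sin(M * rad) +
                         4 * e * y * sin(M * rad) * cos(2 * L0 * rad) -
                         0.5 * y^2 * sin(4 * L0 * rad) -
                         1.25 * e^2 * sin(2 * M * rad))   # minutes
  minutes_utc <- (unix %% 86400) / 60
  tst <- (minutes_utc + eqtime + 4 * longitude_deg) %% 1440
  ha <- tst / 4 - 180
  if (ha < -180) ha <- ha + 360
  cos_zen <- sin(latitude_deg * rad) * sin(decl * rad) +
    cos(latitude_deg * rad) * cos(decl * rad) * cos(ha * rad)
  cos_zen <- min(max(cos_zen, -1), 1)
  zen <- acos(cos_zen) / rad
  altitude <- 90 - zen
  az <- if (sin(zen * rad) < 1e-9) 180 else {
    caz <- (sin(latitude_deg * rad) * cos_zen - sin(decl * rad)) /
      (cos(latitude_deg * rad) * sin(zen * rad))
    caz <- min(max(caz, -1), 1)
    a <- acos(caz) / rad
    if (ha > 0) (a + 180) %% 360 else (180 - a) %% 360
  }
  c(altitude_deg = altitude, azimuth_deg = az)
}

.subset_theta <- c(`RGB-3` = 29.61, `RGB-13` = 29.61,
                   `NDVI-13` = 26.22, `GNDVI-13` = 26.22,
                   RGB = 29.61, NDVI = 26.22, GNDVI = 26.22)

#' Solar altitude constant used for a data subset
#'
#' The pipeline constants for the study's two flights: RGB subsets use
#' 29.61 degrees, the NDVI/GNDVI subsets 26.22 degrees — the assignment that
#' every reported shadow-length/height pair requires. A computed
#' [solar_position] altitude can be passed as `override` and is returned
#' verbatim.
#'
#' @param subset one of `"RGB-3"`, `"RGB-13"`, `"NDVI-13"`, `"GNDVI-13"`
#'   (or the bare sensor family `"RGB"`, `"NDVI"`, `"GNDVI"`).
#' @param override optional numeric altitude in degrees.
#' @return solar altitude in degrees.
#' @export
theta_for_subset <- function(subset, override = NULL) {
  if (!is.null(override)) return(as.numeric(override))
  th <- .subset_theta[subset]
  if (is.na(th)) stop(sprintf("unknown subset '%s'", subset))
  unname(th)
}
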