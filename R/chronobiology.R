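# Solar calendar and diel time categories for high-latitude sites.
#
# Sunrise/sunset from the standard NOAA solar-position equations with the
# conventional -0.833 deg horizon (refraction + solar radius). At polar
# latitudes a civil date may have no sunrise (polar night) or no sunset
# (polar day); those dates form their own diel categories.

# solar declination (rad) and equation of time (min) for a fractional year
# angle gamma (rad)
.solar_terms <- function(gamma) {
  decl <- 0.006918 - 0.399912 * cos(gamma) + 0.070257 * sin(gamma) -
    0.006758 * cos(2 * gamma) + 0.000907 * sin(2 * gamma) -
    0.002697 * cos(3 * gamma) + 0.00148 * sin(3 * gamma)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(gamma) -
                        0.032077 * sin(gamma) - 0.014615 * cos(2 * gamma) -
                        0.040849 * sin(2 * gamma))
  list(decl = decl, eqtime = eqtime)
}

#' Build a solar calendar of sunrise/sunset per civil date
#'
#' Dates on which the sun never clears the -0.833 deg horizon are flagged
#' `polar_night`; dates on which it never drops below are flagged
#' `polar_day`. Sunrise/sunset are returned as POSIXct in UTC.
#'
#' @param lat latitude, degrees (|lat| <= 90).
#' @param lon longitude, degrees east.
#' @param start,end civil Date range (inclusive).
#' @return A `data.frame` of class `solar_calendar`: `date`, `sunrise`,
#'   `sunset`, `flag` in {`normal`, `polar_day`, `polar_night`}.
#' @export
build_calendar <- function(lat, lon, start, end) {
  stopifnot(abs(lat) <= 90)
  start <- as.Date(start); end <- as.Date(end)
  if (end < start) stop("end date before start date")
  dates <- seq(start, end, by = "day")
  doy <- as.integer(format(dates, "%j"))
  yr_len <- ifelse(as.integer(format(dates, "%Y")) %% 4 == 0, 366, 365)
  gamma <- 2 * pi * (doy - 1 + 0.5) / yr_len
  st <- .solar_terms(gamma)
  latr <- lat * pi / 180
  zen <- 90.833 * pi / 180
  cos_ha <- (cos(zen) - sin(latr) * sin(st$decl)) /
    (cos(latr) * cos(st$decl))
  flag <- rep("normal", length(dates))
  flag[cos_ha > 1] <- "polar_night"
  flag[cos_ha < -1] <- "polar_day"
  ha <- acos(pmin(1, pmax(-1, cos_ha))) * 180 / pi  # degrees
  # minutes after 00:00 UTC
  rise_min <- 720 - 4 * (lon + ha) - st$eqtime
  set_min <- 720 - 4 * (lon - ha) - st$eqtime
  day0 <- as.POSIXct(paste(dates, "00:00:00"), tz = "UTC")
  sunrise <- day0 + rise_min * 60
  sunset <- day0 + set_min * 60
  sunrise[flag != "normal"] <- NA
  sunset[flag != "normal"] <- NA
  out <- data.frame(date = dates, sunrise = sunrise, sunset = sunset,
                    flag = flag, stringsAsFactors = FALSE)
  class(out) <- c("solar_calendar", "data.frame")
  out
}

#' Assign a diel time category to timestamps
#'
#' Categories: `polar_day` / `polar_night` when the civil date is so
#' flagged; otherwise `dawn` within +/- `twilight_window` minutes of
#' sunrise, `dusk` within the same window of sunset, `day` between the dawn
#' and dusk windows, `night` otherwise. The six categories partition the
#' day.
#'
#' @param t POSIXct timestamps (UTC).
#' @param cal a [build_calendar()] calendar covering the dates of `t`.
#' @param twilight_window half-window, minutes.
#' @param utc_offset_hours civil-time offset used to pick the calendar
#'   date of each timestamp.
#' @return Character vector of categories.
#' @export
categorize <- function(t, cal, twilight_window = 60, utc_offset_hours = 1) {
  d <- as.Date(t + utc_offset_hours * 3600, tz = "UTC")
  i <- match(d, cal$date)
  if (any(is.na(i))) stop("timestamp date outside the solar calendar")
  out <- character(length(t))
  flag <- cal$flag[i]
  out[flag == "polar_day"] <- "polar_day"
  out[flag == "polar_night"] <- "polar_night"
  nrm <- which(flag == "normal")
  if (length(nrm)) {
    tw <- twilight_window * 60
    tn <- as.numeric(t[nrm])
    sr <- as.numeric(cal$sunrise[i[nrm]])
    ss <- as.numeric(cal$sunset[i[nrm]])
    cat_n <- rep("night", length(nrm))
    cat_n[tn > sr + tw & tn < ss - tw] <- "day"
    cat_n[abs(tn - sr) <= tw] <- "dawn"
    cat_n[abs(tn - ss) <= tw] <- "dusk"
    out[nrm] <- cat_n
  }
  out
}

#' Count calendar days in a date interval
#'
#' @param start,end Dates (or strings coercible to Date).
#' @param inclusive count both endpoints (default) or the difference only.
#' @return Integer day count.
#' @export
count_days <- function(start, end, inclusive = TRUE) {
  start <- as.Date(start); end <- as.Date(end)
  if (end < start) stop("end date before start date")
  as.integer(end - start) + if (inclusive) 1L else 0L
}

#' Extract the polar-night and polar-day intervals from a calendar
#'
#' @param cal a [build_calendar()] calendar.
#' @return A list with `polar_night` and `polar_day`, each `NULL` or
#'   list(start, end, days).
#' @export
polar_intervals <- function(cal) {
  pick <- function(f) {
    d <- cal$date[cal$flag == f]
    if (!length(d)) return(NULL)
    list(start = min(d), end = max(d), days = count_days(min(d), max(d)))
  }
  list(polar_night = pick("polar_night"), polar_day = pick("polar_day"))
}

#' Assign 3-hour (or configurable) diel blocks
#'
#' @param t POSIXct timestamps (UTC).
#' @param block_hours block width in hours (must divide 24).
#' @param utc_offset_hours civil-time offset.
#' @return Integer block index in 1..(24 / block_hours).
#' @export
time_block <- function(t, block_hours = 3, utc_offset_hours = 1) {
  if (24 %% block_hours != 0) stop("block_hours must divide 24")
  loc <- t + utc_offset_hours * 3600
  hr <- as.integer(format(loc, "%H", tz = "UTC"))
  hr %/% block_hours + 1L
}
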