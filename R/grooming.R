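# Sunrise-to-sunset grooming totals and the solar window computation.

# NOAA solar position (spreadsheet equations, Julian-century form).
# Returns sunrise/sunset as minutes after local civil midnight, or NA under
# polar conditions.
.noaa_sun_minutes <- function(date, lat, lon, tz_offset_hours) {
  jd <- as.numeric(julian(as.Date(date), origin = as.Date("2000-01-01"))) +
    2451544.5 + 0.5 - tz_offset_hours / 24
  jc <- (jd - 2451545) / 36525
  gml <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  gma <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  ctr <- sin(gma * pi / 180) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * gma * pi / 180) * (0.019993 - 0.000101 * jc) +
    sin(3 * gma * pi / 180) * 0.000289
  stl <- gml + ctr
  sal <- stl - 0.00569 - 0.00478 * sin((125.04 - 1934.136 * jc) * pi / 180)
  moe <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  oc <- moe + 0.00256 * cos((125.04 - 1934.136 * jc) * pi / 180)
  decl <- asin(sin(oc * pi / 180) * sin(sal * pi / 180)) * 180 / pi
  vy <- tan(oc / 2 * pi / 180)^2
  eqtime <- 4 * (180 / pi) * (vy * sin(2 * gml * pi / 180) -
    2 * ecc * sin(gma * pi / 180) +
    4 * ecc * vy * sin(gma * pi / 180) * cos(2 * gml * pi / 180) -
    0.5 * vy^2 * sin(4 * gml * pi / 180) -
    1.25 * ecc^2 * sin(2 * gma * pi / 180))
  cos_ha <- cos(90.833 * pi / 180) / (cos(lat * pi / 180) * cos(decl * pi / 180)) -
    tan(lat * pi / 180) * tan(decl * pi / 180)
  if (abs(cos_ha) > 1) return(c(NA_real_, NA_real_))
  ha <- acos(cos_ha) * 180 / pi
  noon <- 720 - 4 * lon - eqtime + tz_offset_hours * 60
  c(noon - 4 * ha, noon + 4 * ha)
}

#' Sunrise, sunset and daylength at a site
#'
#' Standard solar-position computation (zenith 90.833 degrees, i.e.
#' refraction-corrected upper-limb sunrise/sunset) for a civil date at
#' given coordinates.
#'
#' @param date Date (or coercible); vectorised.
#' @param lat,lon site coordinates in decimal degrees; defaults are the Da
#'   Gama Park study site on the Cape Peninsula.
#' @param tz civil time of the site: numeric UTC offset in hours (default
#'   2) or an Olson name.
#' @return `data.table`: `date`, `sunrise`, `sunset` (POSIXct in `tz`),
#'   `daylength_h` (hours).
#' @export
solar_window <- function(date, lat = -34.15562, lon = 18.39858,
                         tz = 2) {
  if (abs(lat) >= 66) stop("solar_window: polar latitudes unsupported")
  date <- as.Date(date)
  off <- .offset_hours(date, tz)
  mins <- t(mapply(.noaa_sun_minutes, date = as.list(date),
                   tz_offset_hours = off,
                   MoreArgs = list(lat = lat, lon = lon)))
  if (anyNA(mins)) stop("solar_window: sun never rises/sets on given date")
  midnight <- .local_midnight(date, tz)
  data.table::data.table(
    date = date,
    sunrise = midnight + mins[, 1] * 60,
    sunset = midnight + mins[, 2] * 60,
    daylength_h = (mins[, 2] - mins[, 1]) / 60)
}

# Merge overlapping intervals [s, e]; returns matrix with columns s, e.
.merge_intervals <- function(s, e) {
  o <- order(s)
  s <- s[o]; e <- e[o]
  grp <- cumsum(c(TRUE, s[-1] > cummax(e[-length(e)])))
  cbind(tapply(s, grp, min), tapply(e, grp, max))
}

#' Daily sunrise-to-sunset grooming totals
#'
#' Sums grooming bout durations per individual, day and direction, clipping
#' every bout to the day's solar window so nighttime records (prone to
#' misclassification) are excluded. Overlapping same-direction bouts are
#' merged before summation (with a warning). Active individual-days with no
#' bouts get explicit zeros.
#'
#' @param bouts data.frame: `individual_id`, `start`, `end` (POSIXct UTC or
#'   ISO-8601 strings), `direction` in `{"give", "receive"}`.
#' @param days data.frame of individual-days to report (`individual_id`,
#'   `date`); defaults to all individual-days appearing in `bouts`.
#' @param lat,lon,tz site coordinates and civil time zone for the solar
#'   window.
#' @return `data.table`: `individual_id`, `date`, `give_min`,
#'   `receive_min`, `daylength_h`.
#' @export
daily_grooming_totals <- function(bouts, days = NULL, lat = -34.15562,
                                  lon = 18.39858, tz = 2) {
  dt <- data.table::as.data.table(bouts)
  stopifnot(all(dt$direction %in% c("give", "receive")))
  dt[, `:=`(start = .as_utc(start), end = .as_utc(end))]
  if (any(dt$end <= dt$start)) stop("bout end must be after start")
  dt[, date := .local_date(start, tz)]
  if (is.null(days)) days <- unique(dt[, .(individual_id, date)])
  days <- data.table::as.data.table(days)
  days[, date := as.Date(date)]
  win <- solar_window(sort(unique(c(dt$date, days$date))), lat, lon, tz)

  sum_dir <- function(s, e, rise, set) {
    iv <- .merge_intervals(as.numeric(s), as.numeric(e))
    if (nrow(iv) < length(s))
      warning("overlapping same-direction bouts merged before summation")
    lo <- pmax(iv[, 1], as.numeric(rise))
    hi <- pmin(iv[, 2], as.numeric(set))
    sum(pmax(hi - lo, 0)) / 60
  }
  tot <- dt[win, on = "date", nomatch = 0L][
    , .(minutes = sum_dir(start, end, sunrise[1], sunset[1])),
    by = .(individual_id, date, direction)]
  wide <- data.table::dcast(tot, individual_id + date ~ direction,
                            value.var = "minutes", fill = 0)
  for (col in c("give", "receive"))
    if (!col %in% names(wide)) wide[, (col) := 0]
  out <- merge(days, wide, by = c("individual_id", "date"), all.x = TRUE)
  out[is.na(give), give := 0]
  out[is.na(receive), receive := 0]
  out <- merge(out, win[, .(date, daylength_h)], by = "date")
  out <- out[, .(individual_id, date, give_min = give, receive_min = receive,
                 daylength_h)]
  data.table::setorder(out, individual_id, date)
  out[]
}
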