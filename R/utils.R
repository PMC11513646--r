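# Internal helpers shared across modules.

# Mean Earth radius (m); used by the equirectangular projection and the
# haversine oracle alike.
.R_EARTH <- 6371008.8

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wrap angles to (-pi, pi]
#' @param theta numeric vector of angles in radians.
#' @return numeric vector in (-pi, pi].
#' @keywords internal
wrap_angle <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  # map -pi to +pi so the interval is half-open on the left
  out[out == -pi] <- pi
  out
}

#' z-transform a numeric vector
#'
#' Subtracts the mean and divides by the standard deviation over the supplied
#' values (NAs removed). Constant input is an error: a z-scored predictor with
#' zero variance carries no information and silently returning NaN would
#' corrupt a model matrix.
#'
#' @param x numeric vector.
#' @return numeric vector with mean 0 and SD 1.
#' @export
ztrans <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("ztrans: input has zero variance")
  (x - mean(x, na.rm = TRUE)) / s
}

# Civil-time handling. A `tz` argument throughout the package is either a
# numeric UTC offset in hours (robust everywhere; the study site is UTC+2
# year-round) or an Olson name (requires a working system tz database).
.local_lt <- function(ts, tz) {
  if (is.numeric(tz)) as.POSIXlt(ts + tz * 3600, tz = "UTC")
  else as.POSIXlt(ts, tz = tz)
}

.local_date <- function(ts, tz) {
  lt <- .local_lt(ts, tz)
  as.Date(format(lt, "%Y-%m-%d"))
}

.local_midnight <- function(date, tz) {
  if (is.numeric(tz))
    as.POSIXct(paste(date, "00:00:00"), tz = "UTC") - tz * 3600
  else as.POSIXct(paste(date, "00:00:00"), tz = tz)
}

.offset_hours <- function(date, tz) {
  if (is.numeric(tz)) return(rep(tz, length(date)))
  z <- format(as.POSIXct(paste(date, "12:00:00"), tz = tz), "%z", tz = tz)
  sign <- ifelse(substr(z, 1, 1) == "-", -1, 1)
  sign * (as.numeric(substr(z, 2, 3)) + as.numeric(substr(z, 4, 5)) / 60)
}

# Coerce a timestamp column to POSIXct (UTC). Accepts POSIXct, numeric
# seconds, or ISO-8601 strings.
.as_utc <- function(ts) {
  if (inherits(ts, "POSIXct")) return(as.POSIXct(ts, tz = "UTC"))
  if (is.numeric(ts)) return(as.POSIXct(ts, origin = "1970-01-01", tz = "UTC"))
  out <- as.POSIXct(ts, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                                   "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d"))
  if (anyNA(out)) stop("unparseable timestamps in input")
  out
}
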