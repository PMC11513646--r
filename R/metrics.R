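# Daily movement metrics: total travel distance, step length, sinuosity and
# residence time, computed on regularly resampled path-segments.

#' Step lengths of a path segment
#'
#' Euclidean displacement between consecutive fixes.
#'
#' @param seg data.frame with `x`, `y` (metres), time-ordered; >= 2 points.
#' @return numeric vector of length `nrow(seg) - 1`, in metres.
#' @export
step_lengths <- function(seg) {
  if (nrow(seg) < 2) stop("step_lengths: need >= 2 points")
  sqrt(diff(seg$x)^2 + diff(seg$y)^2)
}

#' Signed turning angles of a path segment
#'
#' Heading changes between consecutive steps, wrapped to (-pi, pi]. Steps of
#' zero length have no heading: consecutive duplicate positions are collapsed
#' before headings are computed (they still count toward distance elsewhere).
#'
#' @param seg data.frame with `x`, `y`, time-ordered; >= 3 points.
#' @return numeric vector of signed angles in radians (possibly shorter than
#'   `nrow(seg) - 2` when duplicate positions were collapsed; empty if fewer
#'   than two distinct steps remain).
#' @export
turning_angles <- function(seg) {
  if (nrow(seg) < 3) stop("turning_angles: need >= 3 points")
  keep <- c(TRUE, diff(seg$x) != 0 | diff(seg$y) != 0)
  x <- seg$x[keep]; y <- seg$y[keep]
  if (length(x) < 3) return(numeric(0))
  h <- atan2(diff(y), diff(x))
  wrap_angle(diff(h))
}

#' Corrected sinuosity index of a path segment
#'
#' `S = 2 * (p * (1 + c) / (1 - c))^(-1/2)` where `p` is the mean step
#' length (metres) and `c` the mean cosine of turning angles. A straight
#' path (`c = 1`) gives 0; a pure back-and-forth path (`c = -1`) has no
#' finite sinuosity and returns `NA` with a warning. Scaling all coordinates
#' by `k` scales `S` by `k^(-1/2)`.
#'
#' @param seg data.frame with `x`, `y`, time-ordered; >= 3 points with at
#'   least one valid turning angle.
#' @return non-negative scalar (dimensionless), or `NA` when undefined.
#' @export
sinuosity <- function(seg) {
  ang <- turning_angles(seg)
  if (length(ang) == 0) return(NA_real_)
  p <- mean(step_lengths(seg))
  if (p <= 0) return(NA_real_)
  cbar <- mean(cos(ang))
  if (cbar >= 1) return(0)
  if (cbar <= -1) {
    warning("sinuosity undefined: mean cosine of turning angles is -1")
    return(NA_real_)
  }
  2 / sqrt(p * (1 + cbar) / (1 - cbar))
}

# Inside-disc time intervals of a polyline around a centre, by exact linear
# interpolation of entry/exit along each straight step. Returns a matrix with
# columns start, end (seconds), merged where contiguous.
.disc_intervals <- function(t, dx, dy, r) {
  n <- length(t)
  ax <- dx[-n]; ay <- dy[-n]
  bx <- dx[-1] - ax; by <- dy[-1] - ay
  a <- bx^2 + by^2
  b <- 2 * (ax * bx + ay * by)
  cc <- ax^2 + ay^2 - r^2
  s_lo <- rep(NA_real_, n - 1L)
  s_hi <- rep(NA_real_, n - 1L)
  stat <- a == 0
  inside_stat <- stat & cc <= 0
  s_lo[inside_stat] <- 0; s_hi[inside_stat] <- 1
  mov <- which(!stat)
  disc <- b[mov]^2 - 4 * a[mov] * cc[mov]
  ok <- disc > 0
  if (any(ok)) {
    i <- mov[ok]
    rt <- sqrt(disc[ok])
    lo <- pmax((-b[i] - rt) / (2 * a[i]), 0)
    hi <- pmin((-b[i] + rt) / (2 * a[i]), 1)
    sel <- hi > lo
    s_lo[i[sel]] <- lo[sel]
    s_hi[i[sel]] <- hi[sel]
  }
  keep <- !is.na(s_lo)
  if (!any(keep)) return(matrix(numeric(0), ncol = 2))
  dt_step <- diff(t)
  st <- t[-n][keep] + s_lo[keep] * dt_step[keep]
  en <- t[-n][keep] + s_hi[keep] * dt_step[keep]
  # merge intervals that touch (continuity across shared vertices); starts
  # are already time-ordered
  m <- length(st)
  ce <- cummax(en)
  gs <- which(c(TRUE, st[-1] > ce[-m] + 1e-9))
  cbind(st[gs], ce[c(gs[-1] - 1L, m)])
}

#' Residence time at each fix of a path segment
#'
#' For each focal fix, the total time the path spends inside the disc of
#' radius `radius` centred on that fix, scanning forward and backward from
#' the focal time: a visit chain extends across excursions outside the disc
#' no longer than `cutoff` seconds and stops at the first longer excursion.
#' Entry/exit times between successive fixes are obtained by exact linear
#' interpolation along the straight step.
#'
#' @param seg data.frame with `t` (seconds), `x`, `y`; >= 5 points
#'   (shorter segments yield no values, matching the minimum five-fix rule).
#' @param radius disc radius in metres.
#' @param cutoff maximum out-of-disc excursion in seconds (default 300,
#'   i.e. 5 minutes).
#' @return numeric vector of residence times in minutes, one per fix; or
#'   `NULL` when the segment has fewer than 5 points.
#' @export
residence_time <- function(seg, radius, cutoff = 300) {
  stopifnot(radius > 0, cutoff > 0)
  n <- nrow(seg)
  if (n < 5) return(NULL)
  t <- seg$t
  vapply(seq_len(n), function(i) {
    iv <- .disc_intervals(t, seg$x - seg$x[i], seg$y - seg$y[i], radius)
    if (nrow(iv) == 0) return(0)
    # interval containing the focal time (the focal point is at distance 0)
    k <- which(iv[, 1] <= t[i] + 1e-9 & iv[, 2] >= t[i] - 1e-9)[1]
    if (is.na(k)) return(0)
    tot <- iv[k, 2] - iv[k, 1]
    j <- k
    while (j < nrow(iv) && iv[j + 1, 1] - iv[j, 2] <= cutoff) {
      j <- j + 1
      tot <- tot + iv[j, 2] - iv[j, 1]
    }
    j <- k
    while (j > 1 && iv[j, 1] - iv[j - 1, 2] <= cutoff) {
      j <- j - 1
      tot <- tot + iv[j, 2] - iv[j, 1]
    }
    tot / 60
  }, numeric(1))
}

#' Daily movement metrics for one individual-day
#'
#' Total travel distance is summed over the full day across all habitats
#' (within resampled segments, never across gaps). The fine-scale metrics --
#' median step length, median sinuosity and median residence time -- are
#' computed over natural-habitat segments only, per the convention that
#' movement in urban space is qualitatively different. Residence time uses a
#' disc radius equal to the individual-day's mean step length over natural
#' segments (configurable), a cut-off of `cutoff` seconds, and only segments
#' with at least five consecutive fixes.
#'
#' @param traj a single individual-day of fixes from [split_days()].
#' @param interval resampling interval in seconds.
#' @param cutoff residence-time cut-off in seconds.
#' @param radius optional fixed disc radius (metres); default `NULL` uses
#'   the individual-day mean natural step length.
#' @return one-row `data.table`: `individual_id`, `date`, `total_distance_m`,
#'   `median_step_m`, `median_sinuosity`, `median_residence_min`, `n_fixes`.
#'   Medians are `NA` when no qualifying natural segment exists.
#' @export
daily_metrics <- function(traj, interval = 60, cutoff = 300, radius = NULL) {
  dt <- data.table::as.data.table(traj)
  stopifnot(length(unique(dt$individual_id)) == 1, length(unique(dt$date)) == 1)
  res <- resample_trajectory(dt, interval)
  .metrics_one_day(res, nrow(dt), cutoff, radius)
}

# Metrics for one individual-day of already-resampled fixes.
.metrics_one_day <- function(res, n_fixes_raw, cutoff, radius) {
  segs <- split(res, res$segment)
  # total distance spans habitat transitions (full-day travel) but never
  # temporal gaps
  interval <- if (nrow(res) >= 2) min(diff(res$t)) else Inf
  contig <- which(diff(res$t) <= interval)
  total <- sum(sqrt(diff(res$x)^2 + diff(res$y)^2)[contig])
  nat <- Filter(function(s) s$habitat[1] == "natural", segs)
  steps <- unlist(lapply(nat, function(s)
    if (nrow(s) >= 2) step_lengths(s) else numeric(0)))
  sins <- unlist(lapply(nat, function(s)
    if (nrow(s) >= 3) sinuosity(s) else NA_real_))
  sins <- sins[!is.na(sins)]
  r_use <- radius %||% (if (length(steps) && mean(steps) > 0) mean(steps) else NA_real_)
  rts <- if (is.finite(r_use))
    unlist(lapply(nat, function(s)
      if (nrow(s) >= 5) residence_time(s, r_use, cutoff) else NULL))
  else numeric(0)
  data.table::data.table(
    individual_id = res$individual_id[1], date = res$date[1],
    total_distance_m = total,
    median_step_m = if (length(steps)) stats::median(steps) else NA_real_,
    median_sinuosity = if (length(sins)) stats::median(sins) else NA_real_,
    median_residence_min = if (length(rts)) stats::median(rts) else NA_real_,
    n_fixes = n_fixes_raw)
}

#' Daily movement metrics for all individual-days
#'
#' The residence-time radius is "the individual's mean step length": by
#' default (`radius_scope = "individual"`) the mean over all of that
#' individual's natural-habitat steps across the study, so the disc size is
#' a stable property of the individual rather than fluctuating with each
#' day's movement (a per-day radius couples residence time to that day's
#' step length by construction); `radius_scope = "day"` uses the
#' individual-day mean instead.
#'
#' @param fixes planar fix table for any number of individuals and days
#'   (columns of [split_days()] output, or raw fixes which are split first).
#' @inheritParams daily_metrics
#' @param radius_scope `"individual"` (default) or `"day"`; ignored when an
#'   explicit `radius` is given.
#' @param tz civil time used if `fixes` still carries timestamps: numeric
#'   UTC offset in hours (default 2) or an Olson name.
#' @return `data.table` with one row per individual-day.
#' @export
daily_metrics_all <- function(fixes, interval = 60, cutoff = 300,
                              radius = NULL,
                              radius_scope = c("individual", "day"),
                              tz = 2) {
  radius_scope <- match.arg(radius_scope)
  dt <- data.table::as.data.table(fixes)
  if (!"t" %in% names(dt)) dt <- split_days(dt, tz = tz)
  nraw <- dt[, .N, by = .(individual_id, date)]
  res <- resample_trajectory(dt, interval)
  r_ind <- NULL
  if (is.null(radius) && radius_scope == "individual") {
    nat <- res[habitat == "natural"]
    r_ind <- nat[, if (.N >= 2) .(sl = sqrt(diff(x)^2 + diff(y)^2)),
                 by = .(individual_id, date, segment)][
                   , .(r = mean(sl)), by = individual_id]
  }
  parts <- split(res, by = c("individual_id", "date"), sorted = TRUE)
  out <- data.table::rbindlist(lapply(parts, function(p) {
    r_use <- radius
    if (is.null(r_use) && !is.null(r_ind))
      r_use <- r_ind[individual_id == p$individual_id[1], r]
    if (length(r_use) == 0) r_use <- NULL
    .metrics_one_day(p, NA_integer_, cutoff, r_use)
  }))
  out[, n_fixes := NULL]
  out <- merge(out, nraw, by = c("individual_id", "date"))
  data.table::setnames(out, "N", "n_fixes")
  out[]
}
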