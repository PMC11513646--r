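# Independent oracles used across the suite. These deliberately use naive
# algorithms (discretisation, double loops, closed forms) and share no code
# with the implementation paths they check.

# Great-circle distance (haversine), metres.
haversine_m <- function(lon1, lat1, lon2, lat2, R = 6371008.8) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * R * asin(sqrt(pmin(1, a)))
}

# Brute-force residence time: discretise the polyline at `step_s` seconds,
# mark inside/outside the disc, form visits as maximal inside runs joined
# across outside runs <= cutoff, starting from the focal time. Returns
# minutes and the number of chained visits.
oracle_residence <- function(seg, i, radius, cutoff, step_s = 0.5) {
  tt <- seq(seg$t[1], seg$t[nrow(seg)], by = step_s)
  xx <- approx(seg$t, seg$x, xout = tt)$y
  yy <- approx(seg$t, seg$y, xout = tt)$y
  inside <- sqrt((xx - seg$x[i])^2 + (yy - seg$y[i])^2) <= radius
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  vis <- which(r$values)
  if (!length(vis)) return(list(minutes = 0, n_visits = 0L))
  focal_idx <- which.min(abs(tt - seg$t[i]))
  fv <- vis[starts[vis] <= focal_idx & ends[vis] >= focal_idx]
  if (!length(fv)) return(list(minutes = 0, n_visits = 0L))
  keep <- fv
  # forward
  j <- which(vis == fv)
  while (j < length(vis)) {
    gap <- (starts[vis[j + 1]] - 1 - ends[vis[j]]) * step_s
    if (gap > cutoff) break
    j <- j + 1
    keep <- c(keep, vis[j])
  }
  # backward
  j <- which(vis == fv)
  while (j > 1) {
    gap <- (starts[vis[j]] - 1 - ends[vis[j - 1]]) * step_s
    if (gap > cutoff) break
    j <- j - 1
    keep <- c(keep, vis[j])
  }
  secs <- sum(r$lengths[keep]) * step_s
  list(minutes = secs / 60, n_visits = length(keep))
}

# Random resampled-style path segment (regular interval, mix of cruising
# and loitering so discs are entered and left repeatedly).
random_segment <- function(n = 30, interval = 60) {
  mode <- sample(c("loiter", "cruise"), n - 1, replace = TRUE,
                 prob = c(0.6, 0.4))
  step <- ifelse(mode == "loiter", runif(n - 1, 0, 8), runif(n - 1, 20, 60))
  ang <- cumsum(runif(n - 1, -pi, pi) * ifelse(mode == "loiter", 1, 0.15))
  data.frame(t = seq(0, by = interval, length.out = n),
             x = c(0, cumsum(step * cos(ang))),
             y = c(0, cumsum(step * sin(ang))))
}

# Brute-force proximity events: per dyad, list frame times where both are
# present and within threshold, form intervals, union those with gap <=
# merge_gap. Plain double loop over frames.
oracle_events <- function(fixes, threshold = 2, merge_gap = 2,
                          frame_interval = 1) {
  ids <- sort(unique(as.character(fixes$individual_id)))
  out <- list()
  for (a in seq_along(ids)) {
    for (b in seq_along(ids)) {
      if (b <= a) next
      tin <- c()
      for (tt in sort(unique(fixes$time))) {
        ra <- fixes[fixes$individual_id == ids[a] & fixes$time == tt, ]
        rb <- fixes[fixes$individual_id == ids[b] & fixes$time == tt, ]
        if (nrow(ra) == 1 && nrow(rb) == 1 &&
            sqrt((ra$x - rb$x)^2 + (ra$y - rb$y)^2) <= threshold)
          tin <- c(tin, tt)
      }
      if (!length(tin)) next
      # intervals of consecutive frames
      iv <- list()
      s <- tin[1]; e <- tin[1]
      for (tt in tin[-1]) {
        if (tt - e <= frame_interval) e <- tt
        else { iv[[length(iv) + 1]] <- c(s, e); s <- tt; e <- tt }
      }
      iv[[length(iv) + 1]] <- c(s, e)
      # union with gap tolerance
      merged <- list(iv[[1]])
      for (k in seq_along(iv)[-1]) {
        last <- merged[[length(merged)]]
        if (iv[[k]][1] - last[2] <= max(merge_gap, frame_interval))
          merged[[length(merged)]][2] <- iv[[k]][2]
        else merged[[length(merged) + 1]] <- iv[[k]]
      }
      for (m in merged)
        out[[length(out) + 1]] <- data.frame(id_a = ids[a], id_b = ids[b],
                                             start = m[1], end = m[2])
    }
  }
  if (!length(out)) return(data.frame(id_a = character(0),
                                      id_b = character(0),
                                      start = numeric(0), end = numeric(0)))
  res <- do.call(rbind, out)
  res[order(res$start, res$id_a, res$id_b), ]
}

# Random multi-individual proximity scenario: short random walks with
# occasional missing fixes, scaled so dyads cross the 2 m threshold.
random_scenario <- function(n_ind = 4, n_t = 40, p_miss = 0.1) {
  rows <- list()
  for (i in seq_len(n_ind)) {
    x <- cumsum(c(runif(1, -4, 4), rnorm(n_t - 1, 0, 1.2)))
    y <- cumsum(c(runif(1, -4, 4), rnorm(n_t - 1, 0, 1.2)))
    keep <- runif(n_t) >= p_miss
    rows[[i]] <- data.frame(individual_id = sprintf("A%02d", i),
                            time = (1:n_t)[keep], x = x[keep], y = y[keep])
  }
  do.call(rbind, rows)
}

# NOAA "general solar position" low-accuracy algorithm (fractional-year
# form) -- an independent published ephemeris, distinct from the
# Julian-century implementation in the package.
oracle_sun_minutes <- function(date, lat, lon, tz_offset_hours) {
  doy <- as.integer(strftime(date, "%j"))
  g <- 2 * pi / 365 * (doy - 1 + (12 - 12) / 24)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  lat_r <- lat * pi / 180
  cos_ha <- cos(90.833 * pi / 180) / (cos(lat_r) * cos(decl)) -
    tan(lat_r) * tan(decl)
  ha <- acos(pmin(1, pmax(-1, cos_ha))) * 180 / pi
  sunrise_utc <- 720 - 4 * (lon + ha) - eqtime
  sunset_utc <- 720 - 4 * (lon - ha) - eqtime
  c(sunrise_utc + tz_offset_hours * 60, sunset_utc + tz_offset_hours * 60)
}

# Rigid rotation of a segment's coordinates about the origin.
rotate_seg <- function(seg, theta, dx = 0, dy = 0) {
  out <- seg
  out$x <- seg$x * cos(theta) - seg$y * sin(theta) + dx
  out$y <- seg$x * sin(theta) + seg$y * cos(theta) + dy
  out
}
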