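# Dyadic close-proximity ("social opportunity") event detection from
# simultaneous multi-individual GPS, at native sampling resolution.

#' Pairwise distances within a position frame
#'
#' @param frame data.frame with one row per individual: `individual_id`,
#'   `x`, `y` (metres) at a single instant.
#' @return `data.table` with columns `id_a`, `id_b` (unordered dyads,
#'   `id_a < id_b`) and `dist_m`; empty when fewer than two individuals.
#' @export
pairwise_distances <- function(frame) {
  dt <- data.table::as.data.table(frame)
  n <- nrow(dt)
  if (n < 2)
    return(data.table::data.table(id_a = character(0), id_b = character(0),
                                  dist_m = numeric(0)))
  cmb <- utils::combn(order(as.character(dt$individual_id)), 2)
  i <- cmb[1, ]; j <- cmb[2, ]
  data.table::data.table(
    id_a = as.character(dt$individual_id[i]),
    id_b = as.character(dt$individual_id[j]),
    dist_m = sqrt((dt$x[i] - dt$x[j])^2 + (dt$y[i] - dt$y[j])^2))
}

#' Detect dyadic social opportunity events
#'
#' A social opportunity event is an episode in which two collared
#' individuals are within `threshold` metres of each other (boundary
#' inclusive). Per dyad, maximal runs of consecutive frames at or under the
#' threshold form raw events; raw events separated by gaps of at most
#' `merge_gap` seconds -- whether caused by a brief separation or by missing
#' fixes -- are merged into a single event.
#'
#' @param fixes fix table for all individuals with `individual_id`, `x`,
#'   `y`, and either `time` (numeric seconds) or `timestamp` (POSIXct);
#'   frames are all fixes sharing a time value.
#' @param threshold proximity threshold in metres (default 2).
#' @param merge_gap maximum gap in seconds between merged events (default 2).
#' @param frame_interval native sampling interval in seconds (default 1).
#' @return `data.table` with one row per merged event: `id_a`, `id_b`
#'   (`id_a < id_b`), `start`, `end` (same time type as the input) and
#'   `duration_s`.
#' @export
detect_events <- function(fixes, threshold = 2, merge_gap = 2,
                          frame_interval = 1) {
  dt <- data.table::as.data.table(fixes)
  tcol <- if ("time" %in% names(dt)) dt$time else as.numeric(dt$timestamp)
  work <- data.table::data.table(id = as.character(dt$individual_id),
                                 tt = as.numeric(tcol), x = dt$x, y = dt$y)
  ids <- sort(unique(work$id))
  if (length(ids) < 2)
    return(data.table::data.table(id_a = character(0), id_b = character(0),
                                  start = numeric(0), end = numeric(0),
                                  duration_s = numeric(0)))
  # wide layout: one row per frame time, one column pair per individual
  times <- sort(unique(work$tt))
  X <- matrix(NA_real_, length(times), length(ids))
  Y <- X
  ti <- match(work$tt, times)
  ii <- match(work$id, ids)
  X[cbind(ti, ii)] <- work$x
  Y[cbind(ti, ii)] <- work$y
  out <- vector("list", length(ids) * (length(ids) - 1) / 2)
  k <- 0L
  gap_brk <- max(frame_interval, merge_gap)
  for (a in seq_len(length(ids) - 1)) {
    for (b in seq((a + 1), length(ids))) {
      d2 <- (X[, a] - X[, b])^2 + (Y[, a] - Y[, b])^2
      inside <- which(!is.na(d2) & d2 <= threshold^2)
      if (!length(inside)) next
      tin <- times[inside]
      # (1) raw events: maximal runs of consecutive frames
      rs <- which(c(TRUE, diff(tin) > frame_interval))
      st <- tin[rs]
      en <- tin[c(rs[-1] - 1L, length(tin))]
      # (2) merge raw events whose separating gap is <= merge_gap
      ms <- which(c(TRUE, st[-1] - en[-length(en)] > gap_brk))
      k <- k + 1L
      out[[k]] <- data.table::data.table(
        id_a = ids[a], id_b = ids[b],
        start = st[ms],
        end = en[c(ms[-1] - 1L, length(st))])
    }
  }
  ev <- data.table::rbindlist(out[seq_len(k)])
  if (nrow(ev) == 0)
    return(data.table::data.table(id_a = character(0), id_b = character(0),
                                  start = numeric(0), end = numeric(0),
                                  duration_s = numeric(0)))
  ev[, duration_s := end - start]
  if (inherits(dt$timestamp %||% tcol, "POSIXct")) {
    ev[, `:=`(start = as.POSIXct(start, origin = "1970-01-01", tz = "UTC"),
              end = as.POSIXct(end, origin = "1970-01-01", tz = "UTC"))]
  }
  data.table::setorder(ev, start, id_a, id_b)
  ev[]
}

#' Daily per-individual social opportunity counts
#'
#' Each merged event increments the daily count of both dyad members.
#' Individuals active on a day but involved in no event get explicit zero
#' rows.
#'
#' @param events output of [detect_events()].
#' @param active data.frame of the collar risk set: `individual_id`, `date`
#'   (one row per active individual-day), e.g. from [active_collars()].
#' @param tz civil time used to date events with POSIXct starts: numeric
#'   UTC offset in hours (default 2) or an Olson name.
#' @return `data.table`: `individual_id`, `date`, `n_events`,
#'   `n_active_collars`.
#' @export
daily_counts <- function(events, active, tz = 2) {
  act <- data.table::as.data.table(active)
  act[, date := as.Date(date)]
  nact <- act[, .(n_active_collars = .N), by = date]
  ev <- data.table::as.data.table(events)
  if (nrow(ev) > 0) {
    ev[, date := if (inherits(start, "POSIXct")) .local_date(start, tz)
      else as.Date(floor(start / 86400), origin = "1970-01-01")]
    long <- data.table::rbindlist(list(
      ev[, .(individual_id = id_a, date)],
      ev[, .(individual_id = id_b, date)]))
    cnt <- long[, .(n_events = .N), by = .(individual_id, date)]
  } else {
    cnt <- data.table::data.table(individual_id = character(0),
                                  date = as.Date(character(0)),
                                  n_events = integer(0))
  }
  out <- merge(act[, .(individual_id, date)], cnt,
               by = c("individual_id", "date"), all.x = TRUE)
  out[is.na(n_events), n_events := 0L]
  out <- merge(out, nact, by = "date")
  data.table::setcolorder(out, c("individual_id", "date", "n_events",
                                 "n_active_collars"))
  data.table::setorder(out, individual_id, date)
  out[]
}

#' Derive the active-collar risk set from GPS data
#'
#' An individual is active on a day if it has at least one fix that day.
#'
#' @param fixes fix table with `individual_id` and `date` (or `timestamp`).
#' @param tz civil time for dating timestamps: numeric UTC offset in
#'   hours (default 2) or an Olson name.
#' @return `data.table` with `individual_id`, `date`.
#' @export
active_collars <- function(fixes, tz = 2) {
  dt <- data.table::as.data.table(fixes)
  if (!"date" %in% names(dt))
    dt[, date := .local_date(timestamp, tz)]
  unique(dt[, .(individual_id = as.character(individual_id), date)])
}

#' Filter opportunity counts to well-sampled days
#'
#' Keeps rows from days on which at least `min_collars` collars were active,
#' the regime in which proximity-derived social measures are robust.
#'
#' @param counts output of [daily_counts()].
#' @param min_collars minimum number of simultaneously active collars
#'   (default 10).
#' @return filtered `data.table`.
#' @export
filter_active <- function(counts, min_collars = 10) {
  dt <- data.table::as.data.table(counts)
  dt[n_active_collars >= min_collars][]
}
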