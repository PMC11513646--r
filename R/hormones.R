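# Faecal fT3 processing: daily means, excretion lag, within-/between-
# individual decomposition, and the age-rank validation statistics.

#' Daily mean fT3 per individual
#'
#' When more than one sample is available for an individual-day, their
#' arithmetic mean is used.
#'
#' @param samples data.frame: `individual_id`, `collection_date`,
#'   `ft3_ng_g` (ng per g faecal dry weight, > 0).
#' @return `data.table`: `individual_id`, `collection_date`, `ft3_ng_g`
#'   (one row per individual-day).
#' @export
daily_mean_ft3 <- function(samples) {
  dt <- data.table::as.data.table(samples)
  if (any(dt$ft3_ng_g <= 0)) stop("ft3 concentrations must be positive")
  dt[, collection_date := as.Date(collection_date)]
  out <- dt[, .(ft3_ng_g = mean(ft3_ng_g)),
            by = .(individual_id, collection_date)]
  data.table::setorder(out, individual_id, collection_date)
  out[]
}

#' Align fT3 samples to behaviour days via the excretion lag
#'
#' Hormone metabolites appear in faeces with a delay: a sample collected on
#' day `d + lag` reflects circulating levels on behaviour day `d`. With the
#' default 48 h lag, behaviour on day `d` is paired with the sample
#' collected on day `d + 2`; behaviour days with no matching sample are
#' dropped. `direction = "backward"` pairs day `d` with the sample from
#' day `d - 2` instead, for sensitivity analyses.
#'
#' @param daily output of [daily_mean_ft3()].
#' @param lag_hours lag in hours; must be a whole number of days
#'   (default 48).
#' @param direction `"forward"` (behaviour day d <- sample day d + lag,
#'   the physiological default) or `"backward"`.
#' @return `data.table`: `individual_id`, `behaviour_date`, `ft3_daily`.
#' @export
apply_lag <- function(daily, lag_hours = 48, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  if (lag_hours %% 24 != 0) stop("lag_hours must be a whole number of days")
  lag_days <- lag_hours / 24
  if (direction == "backward") lag_days <- -lag_days
  dt <- data.table::as.data.table(daily)
  out <- dt[, .(individual_id, behaviour_date = collection_date - lag_days,
                ft3_daily = ft3_ng_g)]
  data.table::setorder(out, individual_id, behaviour_date)
  out[]
}

#' Within-/between-individual decomposition of fT3
#'
#' Splits each lagged daily value into the individual's mean over its
#' included records (the between-individual component) and the deviation of
#' the value from that mean (the within-individual, mean-centred component).
#' The two components reconstruct the value exactly, and centred values sum
#' to zero within each individual.
#'
#' @param lagged output of [apply_lag()] (optionally pre-filtered to the
#'   rows that will enter a model, so the centring invariant holds within
#'   the fitted dataset).
#' @return `data.table`: `individual_id`, `behaviour_date`, `ft3_daily`,
#'   `ft3_mean`, `ft3_centred`.
#' @export
decompose_energy <- function(lagged) {
  dt <- data.table::as.data.table(lagged)
  out <- data.table::copy(dt)
  out[, ft3_mean := mean(ft3_daily), by = individual_id]
  out[, ft3_centred := ft3_daily - ft3_mean]
  out[]
}

#' Rescale values to the unit interval
#'
#' `(x - min) / (max - min)`: the minimum maps to 0, the maximum to 1. Used
#' to standardize ordinal age ranks (0 = youngest, 1 = oldest) and
#' dominance ranks.
#'
#' @param x numeric vector with at least two distinct values.
#' @return numeric vector in `[0, 1]`.
#' @export
range01 <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (r[1] == r[2]) stop("range01: all values equal (degenerate range)")
  (x - r[1]) / (r[2] - r[1])
}

#' Spearman rank correlation with two-sided p-value
#'
#' Tie-aware (average ranks); the p-value uses the large-sample t
#' approximation, appropriate for tied data.
#'
#' @param a,b numeric vectors of equal length >= 3.
#' @return list with elements `rho`, `p`, `n`.
#' @export
spearman_cor <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("spearman_cor: constant input")
  ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(a))
}

#' Standardized mean age ranks from two independent rankings
#'
#' Averages two observers' ordinal age rankings per individual and rescales
#' the mean rank to `[0, 1]` (0 = youngest, 1 = oldest). Also reports the
#' Spearman correlation between the two rankings as an inter-observer
#' reliability check.
#'
#' @param ranks data.frame: `individual_id`, `rank_a`, `rank_b`.
#' @return list with `ranks` (a `data.table` adding
#'   `standardized_mean_rank`) and `observer_agreement` (a [spearman_cor()]
#'   result).
#' @export
age_ranks <- function(ranks) {
  dt <- data.table::as.data.table(ranks)
  agreement <- spearman_cor(dt$rank_a, dt$rank_b)
  dt[, standardized_mean_rank := range01((rank_a + rank_b) / 2)]
  list(ranks = dt[], observer_agreement = agreement)
}
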