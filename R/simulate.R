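# Synthetic data generator: an agent-based cohesive-group movement model
# with a latent daily energy state, mechanistic close-proximity encounters
# and grooming driven by realised social opportunities. All four input
# streams of the analysis pipeline are generated from a single seed with
# known ground-truth effects, enabling end-to-end parameter-recovery and
# type-I-error studies without field data.

#' Generator configuration
#'
#' Defaults emulate the field setting at desk scale: 13 collared adults (11
#' females, 2 males), 30 study days, 1 Hz GPS over a daily tracking window,
#' sparse opportunistic faecal sampling, and day-level collar dropout. The
#' movement model is a two-state correlated walk around a smoothly moving
#' group centroid: in area-restricted search (ARS) an individual hovers
#' tightly around a (by default shared) local anchor, producing short steps,
#' high tortuosity, long residence times and chance <= 2 m encounters; in
#' transit it tracks the centroid, producing long, straight steps. The
#' daily log-odds of ARS are `alpha_M + beta_EM * w[i, d]` where `w` is the
#' individual's within-individual energy deviation, so `beta_EM > 0` makes
#' higher-energy days more residency-prone. Receiving grooming increases
#' linearly in realised opportunity counts with slope `beta_O`; the giving
#' slope is `beta_O + beta_OxE * w[i, d]`.
#'
#' @param n_individuals number of collared adults (default 13).
#' @param n_females number of females among them (default 11).
#' @param n_days number of study days (default 30).
#' @param start_date first behaviour date (default "2018-07-01", austral
#'   winter at the study site).
#' @param gps_rate GPS sampling rate in Hz (default 1).
#' @param day_window_s tracked seconds per day (default 1800; a desk-scale
#'   stand-in for a full tracking day, see the methods vignette).
#' @param day_start_h local start hour of the daily window (default 9).
#' @param mu_pop population mean fT3 (ng/g, default 15).
#' @param sigma_between,sigma_within between-/within-individual energy SDs
#'   (ng/g; defaults 2 and 3).
#' @param age_slope effect of standardized age (0..1) on mean energy
#'   (default -3; older individuals have lower fT3).
#' @param meas_sd assay/measurement noise SD on observed fT3 (default 0.5).
#' @param p_sample probability an individual-day yields a faecal sample
#'   (default 0.5); `p_second_sample` chance of a duplicate sample.
#' @param lag_hours excretion lag used when dating samples (default 48).
#' @param alpha_M baseline ARS log-odds (default -0.4).
#' @param beta_EM energy-to-ARS effect (log-odds per ng/g, default 0.07).
#' @param block_s behavioural bout length in seconds (default 180).
#' @param kappa attraction strength of the movement walk (default 0.25).
#' @param speed centroid travel speed (m/s, default 0.5).
#' @param cluster_sd stationary spread around an ARS anchor (m, default
#'   0.6); smaller values cluster co-resident individuals more tightly and
#'   so strengthen the residence-to-opportunity link.
#' @param p_share probability that an ARS bout uses the shared anchor
#'   rather than a private one (default 0.75); with `share_anchors = FALSE`
#'   it is ignored and all anchors are private. Together with `cluster_sd`
#'   this sets the strength of the mechanistic residence-to-opportunity
#'   link.
#' @param transit_sd individual spread around the centroid in transit (m,
#'   default 10).
#' @param anchor_disp displacement of shared ARS anchors from the centroid
#'   (m, default 6).
#' @param share_anchors logical; `TRUE` (default) makes co-resident
#'   individuals share anchors (the mechanistic residence-to-opportunity
#'   link); `FALSE` gives each individual a private anchor, nullifying it.
#' @param urban_radius radius of the fixed urban disc at the daily start
#'   point (m, default 50); fixes inside it are flagged `urban`.
#' @param p_dropout day-level collar dropout probability (default 0.08).
#' @param a_R,a_G baseline receive/give grooming minutes (defaults 25).
#' @param beta_O grooming minutes per opportunity event (default 0.11).
#' @param beta_OxE energy moderation of the giving slope (minutes per
#'   event per ng/g, default 0.06).
#' @param slope_sd between-individual SD of the grooming slope (default
#'   0.05), giving the fitted random slopes genuine variance.
#' @param groom_sd grooming noise SD in minutes (default 12).
#' @param lat,lon,tz study-site coordinates and civil time zone.
#' @return a `sm_generator_config` list.
#' @export
generator_config <- function(n_individuals = 13, n_females = 11, n_days = 30,
                             start_date = "2018-07-01", gps_rate = 1,
                             day_window_s = 1800, day_start_h = 9,
                             mu_pop = 15, sigma_between = 2, sigma_within = 3,
                             age_slope = -3, meas_sd = 0.5, p_sample = 0.5,
                             p_second_sample = 0.15, lag_hours = 48,
                             alpha_M = -0.4, beta_EM = 0.07, block_s = 180,
                             kappa = 0.25, speed = 0.5, cluster_sd = 0.6,
                             p_share = 0.75, transit_sd = 10, anchor_disp = 6,
                             share_anchors = TRUE, urban_radius = 50,
                             p_dropout = 0.08, a_R = 25, a_G = 25,
                             beta_O = 0.11, beta_OxE = 0.06, slope_sd = 0.05,
                             groom_sd = 12,
                             lat = -34.15562, lon = 18.39858,
                             tz = 2) {
  cfg <- as.list(environment())
  stopifnot(cfg$sigma_between > 0, cfg$sigma_within > 0, cfg$meas_sd >= 0,
            cfg$p_sample >= 0, cfg$p_sample <= 1,
            cfg$p_dropout >= 0, cfg$p_dropout <= 1,
            cfg$n_females <= cfg$n_individuals, cfg$gps_rate > 0)
  class(cfg) <- "sm_generator_config"
  cfg
}

#' Null generator configuration
#'
#' All structural effects zero: `beta_EM = 0` (energy does not drive
#' behaviour), `alpha_M = -20` (the troop is single-state, so residence
#' variation is pure measurement-level noise and carries no mechanistic
#' link to encounters), `share_anchors = FALSE`, and `beta_O = beta_OxE =
#' 0` (grooming unrelated to opportunities). Used for type-I error studies.
#'
#' @param ... overrides passed to [generator_config()].
#' @return a `sm_generator_config`.
#' @export
null_config <- function(...) {
  generator_config(beta_EM = 0, alpha_M = -20, share_anchors = FALSE,
                   beta_O = 0, beta_OxE = 0, slope_sd = 0, ...)
}

.individual_ids <- function(n) sprintf("ID%02d", seq_len(n))

#' Simulate latent energy and the faecal hormone stream
#'
#' Latent daily energy `E[i, d] = mu_pop + age_slope * age01[i] + b[i] +
#' w[i, d]` with `b ~ N(0, sigma_between)` and `w ~ N(0, sigma_within)`.
#' Observed fT3 adds measurement noise and is written to collection date
#' `d + lag` so that [apply_lag()] inverts the excretion delay. Sampling is
#' opportunistic: each individual-day yields 0, 1 or 2 samples.
#'
#' @param config a [generator_config()].
#' @return list with `latent` (individual-day `data.table` including `w`),
#'   `samples` (hormone CSV stream), `individuals` (ids, sex, age ranks,
#'   dominance rank, reproductive state).
#' @export
simulate_energy <- function(config) {
  n <- config$n_individuals
  ids <- .individual_ids(n)
  sex <- c(rep("F", config$n_females), rep("M", n - config$n_females))
  age01 <- range01(sample(seq_len(n)))          # standardized age rank
  # two observers rank ages with occasional local swaps
  noisy_rank <- function() rank(age01 + stats::rnorm(n, 0, 0.12))
  repro <- ifelse(sex == "M", "male",
                  sample(c("acyclic", "cyclic", "pregnant", "lactating"),
                         n, replace = TRUE))
  individuals <- data.table::data.table(
    individual_id = ids, sex = sex, age01 = age01,
    rank_a = noisy_rank(), rank_b = noisy_rank(),
    rank = range01(sample(seq_len(n))),
    reproductive_state = repro)
  dates <- as.Date(config$start_date) + seq_len(config$n_days) - 1
  b_i <- stats::rnorm(n, 0, config$sigma_between)
  grid <- data.table::CJ(individual_id = ids, date = dates)
  grid <- merge(grid, individuals[, .(individual_id, age01)],
                by = "individual_id")
  grid[, b := b_i[match(individual_id, ids)]]
  grid[, w := stats::rnorm(.N, 0, config$sigma_within)]
  grid[, E := config$mu_pop + config$age_slope * age01 + b + w]
  n_samp <- stats::rbinom(nrow(grid), 1, config$p_sample) +
    stats::rbinom(nrow(grid), 1, config$p_sample * config$p_second_sample)
  lag_days <- config$lag_hours / 24
  samples <- grid[rep(seq_len(.N), n_samp)][
    , .(individual_id,
        collection_date = date + lag_days,
        ft3_ng_g = pmax(0.2, E + stats::rnorm(.N, 0, config$meas_sd)))]
  list(latent = grid[, .(individual_id, date, age01, b, w, E)],
       samples = samples[], individuals = individuals)
}

# AR(1) attraction walk toward a time-varying target; vectorised via
# stats::filter. x0 scalar start, target/noise vectors.
.attract_walk <- function(x0, target, noise, kappa) {
  drv <- kappa * target + noise
  as.numeric(stats::filter(drv, 1 - kappa, method = "recursive",
                           init = x0))
}

#' Simulate the cohesive-troop GPS stream
#'
#' One tracking window per day: the group centroid follows a smooth
#' heading-correlated path starting at the (fixed) urban patch; each active
#' individual alternates between ARS and transit in behavioural blocks, with
#' daily ARS probability `plogis(alpha_M + beta_EM * w[i, d])`. Fixes
#' within `urban_radius` of the daily start point are flagged `urban`.
#' Collar dropout removes whole individual-days.
#'
#' @param config a [generator_config()].
#' @param energy output of [simulate_energy()].
#' @return list with `fixes` (a `data.table`: `individual_id`, `date`, `t`
#'   seconds from local midnight, `time` absolute seconds, `x`, `y`,
#'   `habitat`) and `states` (per individual-day realised ARS fraction).
#' @export
simulate_troop <- function(config, energy) {
  n <- config$n_individuals
  ids <- .individual_ids(n)
  dates <- sort(unique(energy$latent$date))
  T_ <- round(config$day_window_s * config$gps_rate)
  dt_s <- 1 / config$gps_rate
  nb <- ceiling(T_ / (config$block_s * config$gps_rate))
  blk <- rep(seq_len(nb), each = config$block_s * config$gps_rate,
             length.out = T_)
  sig_ars <- config$cluster_sd * sqrt(2 * config$kappa - config$kappa^2)
  sig_tr <- 1.0
  t0 <- config$day_start_h * 3600
  urban2 <- config$urban_radius^2
  out <- vector("list", length(dates))
  states <- vector("list", length(dates))
  w_tab <- energy$latent
  for (d in seq_along(dates)) {
    date <- dates[d]
    active <- which(stats::runif(n) >= config$p_dropout)
    if (length(active) < 2) active <- sort(sample(n, 2))
    # centroid path
    h <- cumsum(c(stats::runif(1, 0, 2 * pi), stats::rnorm(T_ - 1, 0, 0.03)))
    sx <- stats::rnorm(1, 0, 10); sy <- stats::rnorm(1, 0, 10)
    cx <- sx + cumsum(config$speed * dt_s * cos(h))
    cy <- sy + cumsum(config$speed * dt_s * sin(h))
    midb <- pmin(round((seq_len(nb) - 0.5) * config$block_s * config$gps_rate),
                 T_)
    ax_sh <- cx[midb] + stats::rnorm(nb, 0, config$anchor_disp)
    ay_sh <- cy[midb] + stats::rnorm(nb, 0, config$anchor_disp)
    w_d <- w_tab[date == dates[d]][match(ids, individual_id), w]
    p_ars <- stats::plogis(config$alpha_M + config$beta_EM * w_d)
    day_rows <- vector("list", length(active))
    ars_frac <- numeric(length(active))
    for (k in seq_along(active)) {
      i <- active[k]
      s_blk <- stats::rbinom(nb, 1, p_ars[i]) == 1
      ars_frac[k] <- mean(s_blk[blk])
      # anchors, one per ARS block: shared with probability p_share (the
      # mechanistic encounter link), otherwise private
      shared_blk <- s_blk & config$share_anchors &
        (stats::runif(nb) < config$p_share)
      anx <- cx[midb] + stats::rnorm(nb, 0, config$transit_sd)
      any_ <- cy[midb] + stats::rnorm(nb, 0, config$transit_sd)
      anx[shared_blk] <- ax_sh[shared_blk]
      any_[shared_blk] <- ay_sh[shared_blk]
      offx <- stats::rnorm(nb, 0, config$transit_sd)
      offy <- stats::rnorm(nb, 0, config$transit_sd)
      s_t <- s_blk[blk]
      tx <- cx + offx[blk]
      ty <- cy + offy[blk]
      tx[s_t] <- anx[blk][s_t]
      ty[s_t] <- any_[blk][s_t]
      nse <- rep(sig_tr, T_)
      nse[s_t] <- sig_ars
      px <- .attract_walk(tx[1] + stats::rnorm(1, 0, 1), tx,
                          stats::rnorm(T_, 0, nse), config$kappa)
      py <- .attract_walk(ty[1] + stats::rnorm(1, 0, 1), ty,
                          stats::rnorm(T_, 0, nse), config$kappa)
      day_rows[[k]] <- data.table::data.table(
        individual_id = ids[i], date = date,
        t = t0 + seq_len(T_) * dt_s, x = px, y = py)
    }
    day <- data.table::rbindlist(day_rows)
    day[, habitat := ifelse((x - sx)^2 + (y - sy)^2 <= urban2,
                            "urban", "natural")]
    out[[d]] <- day
    states[[d]] <- data.table::data.table(
      individual_id = ids[active], date = date, ars_fraction = ars_frac,
      p_ars = p_ars[active])
  }
  fixes <- data.table::rbindlist(out)
  fixes[, time := as.numeric(date) * 86400 + t]
  list(fixes = fixes[], states = data.table::rbindlist(states))
}

#' Simulate grooming bouts from realised opportunity counts
#'
#' Daily totals follow the structural model (receive: `a_R + beta_O *
#' n_events`; give: `a_G + (beta_O + beta_OxE * w) * n_events`), truncated
#' at zero and capped at 80% of daylength, then decomposed into 1-10 min
#' bouts placed without overlap inside the day's solar window.
#'
#' @param config a [generator_config()].
#' @param counts realised opportunity counts (from [daily_counts()] on the
#'   simulated GPS -- the chain is honest: grooming responds to the counts
#'   the pipeline itself will recompute).
#' @param energy output of [simulate_energy()].
#' @return list with `bouts` (bout stream: `individual_id`, `start`, `end`,
#'   `direction`) and `daily_truth` (intended daily minutes).
#' @export
simulate_grooming <- function(config, counts, energy) {
  cnt <- data.table::as.data.table(counts)
  cnt <- merge(cnt, energy$latent[, .(individual_id, date, w)],
               by = c("individual_id", "date"))
  win <- solar_window(sort(unique(cnt$date)), config$lat, config$lon,
                      config$tz)
  cnt <- merge(cnt, win, by = "date")
  cap <- 0.8 * (cnt$daylength_h * 60)
  ids <- unique(cnt$individual_id)
  slope_i <- config$beta_O + stats::rnorm(length(ids), 0, config$slope_sd)
  cnt[, slope := slope_i[match(individual_id, ids)]]
  cnt[, receive_target := pmin(pmax(0, config$a_R + slope * n_events +
                                      stats::rnorm(.N, 0, config$groom_sd)),
                               cap)]
  cnt[, give_target := pmin(pmax(0, config$a_G +
                                   (slope + config$beta_OxE * w) * n_events +
                                   stats::rnorm(.N, 0, config$groom_sd)),
                            cap)]
  place_bouts <- function(total_min, rise, set, id, dir) {
    if (total_min <= 0) return(NULL)
    durs <- numeric(0)
    left <- total_min
    while (left > 0) {
      dmin <- min(stats::runif(1, 1, 10), left)
      durs <- c(durs, dmin)
      left <- left - dmin
    }
    kk <- length(durs)
    slack <- as.numeric(set) - as.numeric(rise) - sum(durs) * 60
    gaps <- diff(c(0, sort(stats::runif(kk, 0, 1)))) * slack
    starts <- as.numeric(rise) + cumsum(gaps) + c(0, cumsum(durs[-kk])) * 60
    data.table::data.table(
      individual_id = id,
      start = as.POSIXct(starts, origin = "1970-01-01", tz = "UTC"),
      end = as.POSIXct(starts + durs * 60, origin = "1970-01-01", tz = "UTC"),
      direction = dir)
  }
  rows <- vector("list", 2 * nrow(cnt))
  for (r in seq_len(nrow(cnt))) {
    rows[[2 * r - 1]] <- place_bouts(cnt$receive_target[r], cnt$sunrise[r],
                                     cnt$sunset[r], cnt$individual_id[r],
                                     "receive")
    rows[[2 * r]] <- place_bouts(cnt$give_target[r], cnt$sunrise[r],
                                 cnt$sunset[r], cnt$individual_id[r], "give")
  }
  list(bouts = data.table::rbindlist(rows),
       daily_truth = cnt[, .(individual_id, date,
                             receive_target, give_target)])
}

#' Simulate a complete four-stream dataset
#'
#' Orchestrates [simulate_energy()], [simulate_troop()], event detection on
#' the simulated GPS, and [simulate_grooming()], under a single seed.
#'
#' @param config a [generator_config()].
#' @param seed integer seed; all randomness flows from it.
#' @return list with the four input streams (`gps`, `hormones`, `bouts`,
#'   `individuals`), the realised `counts`, and `truth` (latent energies,
#'   state fractions and the structural coefficients used).
#' @export
simulate_dataset <- function(config = generator_config(), seed = 1) {
  set.seed(seed)
  energy <- simulate_energy(config)
  troop <- simulate_troop(config, energy)
  events <- detect_events(troop$fixes, threshold = 2, merge_gap = 2,
                          frame_interval = 1 / config$gps_rate)
  act <- unique(troop$fixes[, .(individual_id, date)])
  counts <- daily_counts(events, act, tz = config$tz)
  groom <- simulate_grooming(config, counts, energy)
  list(gps = troop$fixes, hormones = energy$samples, bouts = groom$bouts,
       individuals = energy$individuals, counts = counts, events = events,
       truth = list(latent = energy$latent, states = troop$states,
                    grooming = groom$daily_truth,
                    coefficients = c(beta_EM = config$beta_EM,
                                     beta_O = config$beta_O,
                                     beta_OxE = config$beta_OxE),
                    config = config))
}

#' Run the full analysis pipeline on a simulated (or real) dataset
#'
#' Movement metrics, opportunity detection and counting, hormone
#' lag/decomposition and grooming totals, joined into the analysis dataset.
#'
#' @param streams list with `gps`, `hormones`, `bouts`, `individuals`
#'   (as from [simulate_dataset()]).
#' @param config a [generator_config()] (controls site coordinates, lag and
#'   sampling interval).
#' @param interval metric resampling interval in seconds.
#' @return the assembled analysis `data.table` from [build_dataset()].
#' @export
run_pipeline <- function(streams, config = generator_config(),
                         interval = 60) {
  metrics <- daily_metrics_all(streams$gps, interval = interval,
                               cutoff = 300, tz = config$tz)
  events <- detect_events(streams$gps, threshold = 2, merge_gap = 2,
                          frame_interval = 1 / config$gps_rate)
  act <- unique(data.table::as.data.table(streams$gps)[,
    .(individual_id, date)])
  counts <- daily_counts(events, act, tz = config$tz)
  horm <- decompose_energy(apply_lag(daily_mean_ft3(streams$hormones),
                                     lag_hours = config$lag_hours))
  groom <- daily_grooming_totals(streams$bouts, days = act,
                                 lat = config$lat, lon = config$lon,
                                 tz = config$tz)
  build_dataset(metrics, counts, horm, groom,
                streams$individuals[, .(individual_id, sex,
                                        reproductive_state, rank)])
}
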