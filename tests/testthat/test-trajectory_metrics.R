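# Movement metrics: projection, resampling, step lengths, turning angles,
# sinuosity, residence time and the daily summary.

test_that("project_to_plane maps the origin to (0,0) and matches haversine", {
  origin <- c(18.399, -34.156)
  fx <- data.frame(individual_id = "A",
                   lon = c(18.399, 18.399, 18.401),
                   lat = c(-34.156, -34.155, -34.156))
  out <- project_to_plane(fx, origin = origin)
  expect_equal(out$x[1], 0)
  expect_equal(out$y[1], 0)
  # 0.001 deg of latitude is ~111.2 m
  expect_equal(sqrt(out$x[2]^2 + out$y[2]^2),
               haversine_m(18.399, -34.156, 18.399, -34.155),
               tolerance = 1e-4)
  # longitude displacement against the haversine oracle
  expect_equal(sqrt(out$x[3]^2 + out$y[3]^2),
               haversine_m(18.399, -34.156, 18.401, -34.156),
               tolerance = 1e-4)
})

test_that("projection round-trips and passes planar input through", {
  origin <- c(18.4, -34.15)
  set.seed(11)
  fx <- data.frame(individual_id = "A",
                   lon = 18.4 + runif(50, -0.05, 0.05),
                   lat = -34.15 + runif(50, -0.05, 0.05))
  pl <- project_to_plane(fx, origin = origin)
  back <- unproject_from_plane(pl[, c("x", "y")], origin)
  err <- haversine_m(fx$lon, fx$lat, back$lon, back$lat)
  expect_lt(max(err), 0.1)
  already <- data.frame(individual_id = "A", x = 1:3, y = 4:6)
  expect_identical(project_to_plane(already)$x, 1:3)
  far <- data.frame(individual_id = "A", lon = c(0, 2), lat = c(0, 0))
  expect_warning(project_to_plane(far, origin = c(0, 0)), "distortion")
})

test_that("resample keeps one fix per interval and splits at gaps", {
  # 1 Hz input over 5 min -> one point per minute
  tr <- data.frame(individual_id = "A", date = as.Date("2018-07-01"),
                   t = 0:300, x = (0:300) * 0.5, y = 0, habitat = "natural")
  rs <- resample_trajectory(tr, 60)
  expect_equal(rs$t, seq(0, 300, 60))
  expect_equal(unique(rs$segment), 1L)
  # a 10-min hole -> two segments
  tr2 <- tr[tr$t <= 100 | tr$t >= 700, ]
  tr2$t[tr2$t >= 700] <- tr2$t[tr2$t >= 700] + 0  # keep as is; gap 100..700
  tr2 <- data.frame(individual_id = "A", date = as.Date("2018-07-01"),
                    t = c(0:100, 700:800), x = 0, y = 0, habitat = "natural")
  rs2 <- resample_trajectory(tr2, 60)
  expect_equal(length(unique(rs2$segment)), 2L)
  expect_true(all(diff(rs2[segment == 1, t]) == 60))
  # habitat change breaks a segment
  tr3 <- tr
  tr3$habitat[tr3$t > 150] <- "urban"
  expect_gt(length(unique(resample_trajectory(tr3, 60)$segment)), 1L)
})

test_that("resampling is idempotent on irregular input", {
  set.seed(21)
  for (rep in 1:20) {
    tt <- sort(sample(0:4000, 120))
    tr <- data.frame(individual_id = "A", date = as.Date("2018-07-01"),
                     t = tt, x = cumsum(rnorm(120)), y = cumsum(rnorm(120)),
                     habitat = "natural")
    r1 <- resample_trajectory(tr, 60)
    r2 <- resample_trajectory(r1, 60)
    expect_equal(r2$t, r1$t)
    expect_equal(r2$x, r1$x)
  }
})

test_that("step lengths: 3-4-5 triangle, zeros, and summation oracle", {
  expect_equal(step_lengths(data.frame(x = c(0, 3), y = c(0, 4))), 5)
  expect_equal(step_lengths(data.frame(x = rep(2, 5), y = rep(7, 5))),
               rep(0, 4))
  set.seed(5)
  seg <- random_segment(40)
  total <- 0
  for (i in 2:40) total <- total +
      sqrt((seg$x[i] - seg$x[i - 1])^2 + (seg$y[i] - seg$y[i - 1])^2)
  expect_equal(sum(step_lengths(seg)), total)
})

test_that("turning angles: collinear, right turns, rotation invariance", {
  line <- data.frame(x = seq(0, 50, 10), y = seq(0, 25, 5))
  expect_equal(turning_angles(line), rep(0, 4))
  left <- data.frame(x = c(0, 1, 1), y = c(0, 0, 1))
  expect_equal(turning_angles(left), pi / 2)
  right <- data.frame(x = c(0, 1, 1), y = c(0, 0, -1))
  expect_equal(turning_angles(right), -pi / 2)
  set.seed(31)
  for (rep in 1:10) {
    seg <- random_segment(15)
    th <- runif(1, 0, 2 * pi)
    expect_equal(turning_angles(rotate_seg(seg, th, 100, -50)),
                 turning_angles(seg), tolerance = 1e-9)
  }
  # duplicate positions are collapsed, not fatal
  dup <- data.frame(x = c(0, 1, 1, 2), y = c(0, 0, 0, 1))
  expect_length(turning_angles(dup), 1)
})

test_that("sinuosity: straight 0, unit zigzag 2, scaling law, c = -1", {
  straight <- data.frame(x = 0:10, y = rep(0, 11))
  expect_equal(sinuosity(straight), 0)
  # unit steps with alternating +-90 degree turns: p = 1, c = 0 -> S = 2
  zig <- data.frame(x = c(0, 1, 1, 2, 2, 3, 3), y = c(0, 0, 1, 1, 2, 2, 3))
  expect_equal(sinuosity(zig), 2)
  set.seed(41)
  for (rep in 1:10) {
    seg <- random_segment(25)
    k <- runif(1, 0.2, 8)
    scaled <- seg
    scaled$x <- seg$x * k; scaled$y <- seg$y * k
    expect_equal(sinuosity(scaled), sinuosity(seg) / sqrt(k),
                 tolerance = 1e-9)
  }
  backforth <- data.frame(x = c(0, 1, 0, 1), y = c(0, 0, 0, 0))
  expect_warning(s <- sinuosity(backforth), "undefined")
  expect_true(is.na(s))
})

test_that("residence time: stationary, straight cruise, excursion cutoff", {
  # stationary for 60 min: residence = full hour everywhere
  n <- 61
  stat <- data.frame(t = seq(0, 3600, 60), x = rep(0, n), y = rep(0, n))
  rt <- residence_time(stat, radius = 5, cutoff = 300)
  expect_equal(rt, rep(60, n))
  # constant-speed straight line, radius = one step: interior fixes ~2 min
  line <- data.frame(t = seq(0, 600, 60), x = seq(0, 600, 60), y = 0)
  rt2 <- residence_time(line, radius = 60, cutoff = 300)
  expect_equal(rt2[6], 2, tolerance = 0.01)
  # an excursion of 4 min returns within the 5-min cutoff; 6 min does not
  mk_loop <- function(away_min) {
    # sit at origin 0-120 s, leave to 1000 m, come back after away_min
    t_out <- 120 + away_min * 60
    data.frame(t = c(0, 60, 120, 120 + 30, t_out - 30, t_out, t_out + 60),
               x = c(0, 0, 0, 1000, 1000, 0, 0), y = 0)
  }
  r4 <- residence_time(mk_loop(4), radius = 50, cutoff = 300)
  r6 <- residence_time(mk_loop(6), radius = 50, cutoff = 300)
  expect_gt(r4[1], r6[1] + 1)  # second visit counted only with short excursion
  expect_null(residence_time(data.frame(t = 1:4, x = 1:4, y = 1:4), 1, 300))
})

test_that("residence time matches the brute-force oracle on random segments", {
  set.seed(51)
  for (rep in 1:15) {
    seg <- random_segment(20)
    radius <- mean(step_lengths(seg))
    rt <- residence_time(seg, radius, cutoff = 300)
    for (i in c(1, 7, 14, 20)) {
      orc <- oracle_residence(seg, i, radius, 300, step_s = 0.5)
      expect_lt(abs(rt[i] - orc$minutes),
                (max(1, orc$n_visits) * 1 + 1) / 60)
    }
  }
})

test_that("metrics are invariant under rigid motions", {
  set.seed(61)
  seg <- random_segment(25)
  seg$individual_id <- "A"; seg$date <- as.Date("2018-07-01")
  seg$habitat <- "natural"
  m1 <- daily_metrics(seg)
  rot <- rotate_seg(seg, 1.1, 500, -200)
  m2 <- daily_metrics(rot)
  for (col in c("total_distance_m", "median_step_m", "median_sinuosity",
                "median_residence_min"))
    expect_equal(m1[[col]], m2[[col]], tolerance = 1e-9)
})

test_that("daily metrics: urban-only days, straight paths, hand summary", {
  day <- data.frame(individual_id = "A", date = as.Date("2018-07-01"),
                    t = seq(0, 1200, 60), x = seq(0, 1200, 60), y = 0,
                    habitat = "urban")
  m <- daily_metrics(day)
  expect_equal(m$total_distance_m, 1200)
  expect_true(is.na(m$median_step_m) && is.na(m$median_sinuosity) &&
                is.na(m$median_residence_min))
  day$habitat <- "natural"
  m2 <- daily_metrics(day)
  expect_equal(m2$median_sinuosity, 0)
  expect_equal(m2$median_step_m, 60)
  # mixed-habitat day: medians use natural fixes only
  mixed <- day
  mixed$habitat <- rep(c("natural", "urban"), length.out = nrow(mixed))
  m3 <- daily_metrics(mixed)
  expect_equal(m3$total_distance_m, 1200)  # distance spans habitats
  expect_true(is.na(m3$median_sinuosity))  # no natural run of >= 3 fixes
})

test_that("daily_metrics_all reproduces an independent per-day summary", {
  set.seed(71)
  rows <- list()
  for (d in 1:3) {
    seg <- random_segment(30)
    rows[[d]] <- data.frame(individual_id = "A",
                            date = as.Date("2018-07-01") + d,
                            t = seg$t + 8 * 3600, x = seg$x, y = seg$y,
                            habitat = "natural")
  }
  fx <- do.call(rbind, rows)
  all_m <- daily_metrics_all(fx, radius_scope = "day")
  expect_equal(nrow(all_m), 3)
  # independent recomputation, one day at a time
  for (d in 1:3) {
    one <- daily_metrics(rows[[d]])
    expect_equal(all_m[d, ]$median_residence_min, one$median_residence_min)
    expect_equal(all_m[d, ]$total_distance_m, one$total_distance_m)
  }
})
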