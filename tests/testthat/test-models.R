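# Dataset assembly, mixed-model fitting, LRTs and collinearity diagnostics.

# Small synthetic mixed-model data with known fixed effects and controllable
# random-effect variances.
sim_lmm_rows <- function(n_id = 8, n_day = 20, beta = 0.5, sd_id = 0,
                         sd_day = 0, sd_e = 1, seed = 1) {
  set.seed(seed)
  g <- expand.grid(individual_id = sprintf("I%02d", seq_len(n_id)),
                   date = as.Date("2018-07-01") + seq_len(n_day))
  g$x <- rnorm(nrow(g))
  ri <- rnorm(n_id, 0, sd_id)
  rd <- rnorm(n_day, 0, sd_day)
  g$y <- 2 + beta * g$x + ri[as.integer(factor(g$individual_id))] +
    rd[as.integer(factor(g$date))] + rnorm(nrow(g), 0, sd_e)
  g
}

simple_spec <- function(transform = "identity", slope = "x") {
  specs <- model_specs()
  sp <- specs$LMM6
  sp$name <- "TEST"
  sp$response <- "y"
  sp$transform <- transform
  sp$focal <- "x"
  sp$controls <- character(0)
  sp$slope <- slope
  sp$sex <- "all"
  sp$interaction <- NULL
  sp
}

test_that("build_dataset joins the four streams on individual-days", {
  metrics <- data.frame(individual_id = c("A", "A", "B"),
                        date = as.Date("2018-07-01") + c(0, 1, 0),
                        total_distance_m = c(100, 200, 300),
                        median_step_m = 1, median_sinuosity = 0.2,
                        median_residence_min = c(2, 4, 8), n_fixes = 10)
  counts <- data.frame(individual_id = c("A", "B"),
                       date = as.Date("2018-07-01"),
                       n_events = c(3L, 5L), n_active_collars = 11L)
  energy <- data.frame(individual_id = "A",
                       behaviour_date = as.Date("2018-07-02"),
                       ft3_daily = 16, ft3_mean = 15, ft3_centred = 1)
  groom <- data.frame(individual_id = "B", date = as.Date("2018-07-01"),
                      give_min = 12, receive_min = 30, daylength_h = 10)
  meta <- data.frame(individual_id = c("A", "B"), sex = c("F", "F"),
                     reproductive_state = c("cyclic", "pregnant"),
                     rank = c(0.2, 0.9))
  ds <- build_dataset(metrics, counts, energy, groom, meta)
  expect_equal(nrow(ds), 3)
  a2 <- ds[ds$individual_id == "A" & ds$date == as.Date("2018-07-02"), ]
  expect_equal(a2$ft3_centred, 1)
  expect_true(is.na(a2$n_events))
  b1 <- ds[ds$individual_id == "B", ]
  expect_equal(b1$receive_min, 30)
  expect_equal(b1$rank, 0.9)
})

test_that("model frames z-score predictors and transform responses", {
  rows <- sim_lmm_rows(n_id = 6, n_day = 15, seed = 2)
  rows$y <- abs(rows$y) + 1
  sp <- simple_spec(transform = "log")
  mf <- sociomove:::.model_frame(sp, rows, ztransform = TRUE)
  expect_equal(mean(mf$frame$x), 0, tolerance = 1e-12)
  expect_equal(sd(mf$frame$x), 1, tolerance = 1e-12)
  expect_equal(mf$frame$.resp, log(rows$y))
  # zero responses under log are dropped and counted
  rows2 <- rows
  rows2$y[1:3] <- 0
  mf2 <- sociomove:::.model_frame(sp, rows2, ztransform = TRUE)
  expect_equal(mf2$n_dropped_zero, 3)
  expect_equal(nrow(mf2$frame), nrow(rows) - 3)
})

test_that("fit_lmm recovers a known slope and is order-invariant", {
  rows <- sim_lmm_rows(beta = 0.5, seed = 3)
  f <- fit_lmm(simple_spec(), rows, ztransform = FALSE)
  est <- f$coefficients[f$coefficients$term == "x", ]
  expect_lt(abs(est$estimate - 0.5), 3 * est$se)
  expect_equal(f$n_individuals, 8)
  expect_equal(f$n_obs, 160)
  # response equal to the predictor (plus negligible noise): slope ~1
  rows2 <- rows
  rows2$y <- rows2$x + rnorm(nrow(rows2), 0, 1e-4)
  f2 <- suppressWarnings(fit_lmm(simple_spec(slope = NULL), rows2,
                                 ztransform = FALSE))
  expect_equal(f2$coefficients[f2$coefficients$term == "x", ]$estimate, 1,
               tolerance = 1e-4)
  # permuting rows changes nothing
  f3 <- fit_lmm(simple_spec(), rows[sample(nrow(rows)), ],
                ztransform = FALSE)
  expect_equal(f3$coefficients$estimate, f$coefficients$estimate,
               tolerance = 1e-5)
})

test_that("z-scored and raw fits are equivalent up to the SD factor", {
  rows <- sim_lmm_rows(beta = 0.4, seed = 5)
  rows$x <- rows$x * 3.7 + 11   # arbitrary location/scale
  fz <- fit_lmm(simple_spec(slope = NULL), rows, ztransform = TRUE)
  fr <- fit_lmm(simple_spec(slope = NULL), rows, ztransform = FALSE)
  bz <- fz$coefficients[fz$coefficients$term == "x", ]$estimate
  br <- fr$coefficients[fr$coefficients$term == "x", ]$estimate
  expect_equal(bz, br * sd(rows$x), tolerance = 1e-6)
  # and the same identity in a fixed-effects-only fit
  lm_z <- coef(lm(y ~ scale(x), rows))[2]
  lm_r <- coef(lm(y ~ x, rows))[2]
  expect_equal(unname(lm_z), unname(lm_r) * sd(rows$x), tolerance = 1e-9)
})

test_that("lrt: identical models give chi2 0, nesting is enforced", {
  rows <- sim_lmm_rows(beta = 0, sd_id = 0.5, seed = 7)
  f <- fit_lmm(simple_spec(), rows, ztransform = FALSE)
  same <- lrt(f$fit, f$fit)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  # independent deviance-difference computation on a fixed pair
  full <- lme4::lmer(y ~ x + (1 | individual_id), rows, REML = FALSE)
  null <- lme4::lmer(y ~ 1 + (1 | individual_id), rows, REML = FALSE)
  got <- lrt(full, null)
  want_chi2 <- as.numeric(2 * (logLik(full) - logLik(null)))
  expect_equal(got$chi2, max(0, want_chi2), tolerance = 1e-9)
  expect_equal(got$df, 1)
  expect_equal(got$p, pchisq(got$chi2, 1, lower.tail = FALSE))
  expect_error(lrt(null, full), "more parameters")
})

test_that("a strong simulated effect is detected by the LRT", {
  hits <- 0
  for (s in 1:10) {
    rows <- sim_lmm_rows(beta = 1, sd_id = 0.3, sd_e = 1, seed = 100 + s)
    f <- fit_lmm(simple_spec(), rows, ztransform = FALSE)
    if (f$lrt$p < 0.001) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("VIFs: orthogonal 1, r = 0.6 gives 1.5625, duplicates infinite", {
  n <- 200
  x1 <- rep(c(-1, 1), each = n / 2)
  x2 <- rep(c(-1, 1), times = n / 2)
  m <- cbind(`(Intercept)` = 1, x1 = x1, x2 = x2)
  v <- vif_fixed(m, assign = c(0, 1, 2))
  expect_equal(unname(v), c(1, 1))
  # build a pair with sample correlation exactly 0.6
  set.seed(41)
  a <- scale(rnorm(n))[, 1]
  b0 <- scale(resid(lm(rnorm(n) ~ a)))[, 1]
  b <- 0.6 * a + sqrt(1 - 0.36) * b0
  m2 <- cbind(`(Intercept)` = 1, a = a, b = b)
  v2 <- vif_fixed(m2, assign = c(0, 1, 2))
  expect_equal(unname(v2), rep(1 / (1 - 0.6^2), 2), tolerance = 1e-6)
  m3 <- cbind(`(Intercept)` = 1, a = a, b = a)
  v3 <- vif_fixed(m3, assign = c(0, 1, 2))
  expect_true(all(is.infinite(v3)))
})

test_that("run_suite reports Table-1-style rows per model", {
  skip_if_not_installed("lme4")
  set.seed(43)
  sim <- simulate_dataset(generator_config(n_days = 12), seed = 99)
  data <- run_pipeline(sim)
  suite <- run_suite(data, model_specs(min_collars = 10),
                     models = c("LMM4", "LMM6"))
  rep <- suite$report
  expect_true(all(c("model", "term", "estimate", "se", "t", "p", "lrt_df",
                    "lrt_chi2", "lrt_p", "max_vif", "N", "n") %in%
                    names(rep)))
  expect_setequal(unique(rep$model), c("LMM4", "LMM6"))
  expect_true("reproductive_state (overall)" %in% rep$term)
  expect_true(all(rep$N >= 2))
  expect_true(all(rep$max_vif >= 1, na.rm = TRUE))
  f4 <- suite$fits$LMM4
  expect_equal(f4$lrt$df, 4)   # two fT3 fixed effects + slope var + corr
})
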