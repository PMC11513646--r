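# The chained linear mixed-model suite: dataset assembly, model
# specifications, REML fits with crossed random effects and random slopes,
# likelihood-ratio tests against null models, and collinearity diagnostics.

#' Assemble the joined analysis dataset
#'
#' Inner-joins the four processed streams on individual-day keys and attaches
#' individual metadata. No transforms are applied here; each model applies
#' its own response transform and z-scores its continuous predictors over
#' its included rows (see [fit_lmm()]).
#'
#' @param metrics output of [daily_metrics_all()].
#' @param counts output of [daily_counts()] (unfiltered; models apply their
#'   own collar filter).
#' @param energy output of [decompose_energy()] (lagged fT3 covariates).
#' @param grooming output of [daily_grooming_totals()].
#' @param metadata data.frame per individual: `individual_id`, `sex`
#'   (`"F"`/`"M"`), `reproductive_state` (acyclic, cyclic, pregnant,
#'   lactating, male), `rank` (standardized `[0, 1]`).
#' @return `data.table` keyed by `individual_id`, `date` with all response
#'   and covariate columns; streams are outer-joined so each model can take
#'   the complete-case subset for its own variables.
#' @export
build_dataset <- function(metrics, counts = NULL, energy = NULL,
                          grooming = NULL, metadata = NULL) {
  out <- data.table::as.data.table(metrics)
  out[, date := as.Date(date)]
  if (!is.null(counts)) {
    cnt <- data.table::as.data.table(counts)
    cnt[, date := as.Date(date)]
    out <- merge(out, cnt, by = c("individual_id", "date"), all = TRUE)
  }
  if (!is.null(energy)) {
    en <- data.table::as.data.table(energy)
    en <- en[, .(individual_id, date = as.Date(behaviour_date),
                 ft3_daily, ft3_mean, ft3_centred)]
    out <- merge(out, en, by = c("individual_id", "date"), all.x = TRUE)
  }
  if (!is.null(grooming)) {
    gr <- data.table::as.data.table(grooming)
    gr[, date := as.Date(date)]
    out <- merge(out, gr, by = c("individual_id", "date"), all.x = TRUE)
  }
  if (!is.null(metadata)) {
    md <- data.table::as.data.table(metadata)
    out <- merge(out, md, by = "individual_id", all.x = TRUE)
  }
  data.table::setorder(out, individual_id, date)
  out[]
}

#' Specifications of the seven-model suite
#'
#' LMM1-LMM4 relate the four daily movement metrics to the decomposed,
#' lagged fT3 covariates (all individuals; random slope for mean-centred
#' fT3 within individual). LMM5 relates daily social opportunity frequency
#' to residence time (females only, >= `min_collars` active collars; random
#' slope for residence time). LMM6 and LMM7 relate grooming received/given
#' to opportunity frequency (females; random slope for opportunities), with
#' LMM7 adding the focal fT3-by-opportunity interaction. Null models contain
#' the random intercepts and control fixed effects only; the full model adds
#' the focal fixed effect(s) and the focal random slope.
#'
#' @param interaction_ft3 which fT3 component enters LMM7's interaction:
#'   `"ft3_centred"` (default) or `"ft3_mean"`.
#' @param min_collars collar filter for LMM5 (default 10).
#' @return named list of `sm_model_spec` objects.
#' @export
model_specs <- function(interaction_ft3 = c("ft3_centred", "ft3_mean"),
                        min_collars = 10) {
  interaction_ft3 <- match.arg(interaction_ft3)
  spec <- function(name, response, transform, focal, controls, slope,
                   sex = "all", collar_filter = NA_real_,
                   interaction = NULL) {
    structure(list(name = name, response = response, transform = transform,
                   focal = focal, controls = controls, slope = slope,
                   sex = sex, collar_filter = collar_filter,
                   interaction = interaction),
              class = "sm_model_spec")
  }
  movement <- function(name, response, transform)
    spec(name, response, transform,
         focal = c("ft3_mean", "ft3_centred"),
         controls = "reproductive_state", slope = "ft3_centred")
  list(
    LMM1 = movement("LMM1", "total_distance_m", "identity"),
    LMM2 = movement("LMM2", "median_step_m", "log"),
    LMM3 = movement("LMM3", "median_sinuosity", "log"),
    LMM4 = movement("LMM4", "median_residence_min", "log"),
    LMM5 = spec("LMM5", "n_events", "sqrt",
                focal = "log_residence",
                controls = c("daylength_h", "reproductive_state", "rank",
                             "n_active_collars"),
                slope = "log_residence", sex = "F",
                collar_filter = min_collars),
    LMM6 = spec("LMM6", "receive_min", "sqrt",
                focal = "n_events",
                controls = c("daylength_h", "reproductive_state", "rank"),
                slope = "n_events", sex = "F"),
    LMM7 = spec("LMM7", "give_min", "sqrt",
                focal = paste0("n_events:", interaction_ft3),
                controls = c("n_events", interaction_ft3, "daylength_h",
                             "reproductive_state", "rank"),
                slope = "n_events", sex = "F",
                interaction = c("n_events", interaction_ft3)))
}

.apply_transform <- function(y, transform) {
  switch(transform,
         identity = y,
         log = { y[y <= 0] <- NA; log(y) },
         sqrt = { y[y < 0] <- NA; sqrt(y) },
         stop("unknown transform: ", transform))
}

# Build the model frame for a spec: sex/collar filters, response transform,
# complete cases, z-scoring of continuous predictors. Returns list(frame,
# n_dropped_zero, scalers).
.model_frame <- function(spec, data, ztransform = TRUE) {
  dt <- data.table::as.data.table(data)
  if (spec$sex == "F" && "sex" %in% names(dt)) dt <- dt[sex == "F"]
  if (is.finite(spec$collar_filter))
    dt <- dt[n_active_collars >= spec$collar_filter]
  if (spec$response == "n_events" || "log_residence" %in%
      c(spec$focal, spec$controls, spec$slope)) {
    if (!"log_residence" %in% names(dt) && "median_residence_min" %in% names(dt))
      dt[, log_residence := .apply_transform(median_residence_min, "log")]
  }
  vars <- setdiff(unique(c(spec$focal, spec$controls, spec$slope,
                           spec$interaction)), NULL)
  vars <- unlist(strsplit(vars, ":", fixed = TRUE))
  resp <- .apply_transform(dt[[spec$response]], spec$transform)
  n_zero <- sum(is.na(resp) & !is.na(dt[[spec$response]]))
  dt[, .resp := resp]
  need <- unique(c(".resp", vars, "individual_id", "date"))
  dt <- dt[stats::complete.cases(dt[, need, with = FALSE])]
  mode <- if (isTRUE(ztransform)) "z" else if (isFALSE(ztransform)) "none"
    else match.arg(ztransform, c("z", "center", "none"))
  scalers <- list()
  for (v in vars) {
    if (!is.numeric(dt[[v]])) {
      dt[, (v) := droplevels(factor(get(v)))]
    } else if (mode != "none") {
      mu <- mean(dt[[v]]); sdv <- stats::sd(dt[[v]])
      scalers[[v]] <- c(mean = mu, sd = sdv)
      if (mode == "z" && sdv > 0) dt[, (v) := (get(v) - mu) / sdv]
      if (mode == "center") dt[, (v) := get(v) - mu]
    }
  }
  dt[, individual_id := factor(individual_id)]
  dt[, date := factor(as.character(date))]
  list(frame = dt, n_dropped_zero = n_zero, scalers = scalers)
}

# Fixed-effect terms usable in a formula, dropping factors with < 2 levels.
.usable_terms <- function(terms, frame) {
  keep <- vapply(terms, function(tm) {
    v <- strsplit(tm, ":", fixed = TRUE)[[1]]
    all(vapply(v, function(x)
      is.numeric(frame[[x]]) || nlevels(frame[[x]]) >= 2, logical(1)))
  }, logical(1))
  terms[keep]
}

.build_formula <- function(response, fixed, slope = NULL,
                           correlated = TRUE) {
  re <- if (is.null(slope)) "(1 | individual_id)" else if (correlated)
    sprintf("(1 + %s | individual_id)", slope) else
      sprintf("(1 + %s || individual_id)", slope)
  stats::as.formula(paste(response, "~",
                          paste(c(fixed, re, "(1 | date)"), collapse = " + ")))
}

#' Fit one linear mixed model of the suite
#'
#' REML fit with crossed random intercepts for individual and date and the
#' spec's random slope (correlated with the intercept; a singular fit --
#' typically a slope variance estimated at zero -- is retained but flagged,
#' keeping the declared parameter count and hence the LRT df). Response
#' transform and z-scoring of continuous predictors are applied to the
#' model's included rows. Per-coefficient p-values use the normal
#' approximation on the t statistic. The null model (random intercepts +
#' controls) is fitted alongside and compared by a maximum-likelihood
#' likelihood-ratio test; the overall p for `reproductive_state` is a
#' likelihood-ratio test dropping that term.
#'
#' @param spec an `sm_model_spec` from [model_specs()].
#' @param data output of [build_dataset()].
#' @param ztransform scaling of continuous predictors: `TRUE`/`"z"`
#'   (z-score, the default), `"center"` (subtract the mean, keep raw units
#'   -- the sound parametrization for raw-scale random-slope fits), or
#'   `FALSE`/`"none"`.
#' @param null_random `"intercepts"` (default; the null model drops the
#'   focal random slope, so the LRT df counts fixed and random parameters
#'   of the focal term together) or `"same"`.
#' @return an `sm_model_fit` list: `name`, `coefficients` (data.table with
#'   estimate, SE, t, p), `term_tests` (overall categorical-term LRTs),
#'   `lrt` (df, chi2, p vs null), `vif`, `n_individuals`, `n_obs`,
#'   `n_dropped_zero`, `singular`, `converged`, `fit` (the merMod),
#'   `scalers`.
#' @export
fit_lmm <- function(spec, data, ztransform = TRUE,
                    null_random = c("intercepts", "same")) {
  null_random <- match.arg(null_random)
  mf <- .model_frame(spec, data, ztransform)
  frame <- mf$frame
  if (nrow(frame) == 0) stop(spec$name, ": no rows after filtering")
  controls <- .usable_terms(spec$controls, frame)
  focal <- .usable_terms(spec$focal, frame)
  full_f <- .build_formula(".resp", c(controls, focal), spec$slope)
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore",
                            check.scaleX = "ignore")
  fit_one <- function(f) {
    warn <- character(0)
    fit <- withCallingHandlers(
      lme4::lmer(f, data = frame, REML = TRUE, control = ctrl),
      warning = function(w) {
        warn <<- c(warn, conditionMessage(w)); invokeRestart("muffleWarning")
      })
    list(fit = fit, warnings = warn)
  }
  res <- fit_one(full_f)
  fit <- res$fit
  co <- summary(fit)$coefficients
  coefs <- data.table::data.table(
    term = rownames(co), estimate = co[, "Estimate"],
    se = co[, "Std. Error"], t = co[, "t value"],
    p = 2 * stats::pnorm(-abs(co[, "t value"])))

  # ML refits for the LRTs
  null_slope <- if (null_random == "same") spec$slope else NULL
  null_f <- .build_formula(".resp", if (length(controls)) controls else "1",
                           null_slope)
  full_ml <- lme4::refitML(fit)
  null_ml <- lme4::lmer(null_f, data = frame, REML = FALSE, control = ctrl)
  lrt_res <- lrt(full_ml, null_ml)

  term_tests <- list()
  for (tm in intersect("reproductive_state", controls)) {
    red_f <- .build_formula(".resp", setdiff(c(controls, focal), tm),
                            spec$slope)
    red_ml <- lme4::lmer(red_f, data = frame, REML = FALSE, control = ctrl)
    term_tests[[tm]] <- lrt(full_ml, red_ml)
  }

  vifs <- tryCatch(vif_fixed(fit), error = function(e) NULL)
  structure(list(
    name = spec$name, spec = spec, coefficients = coefs,
    term_tests = term_tests, lrt = lrt_res, vif = vifs,
    n_individuals = length(unique(as.character(frame$individual_id))),
    n_obs = nrow(frame), n_dropped_zero = mf$n_dropped_zero,
    singular = lme4::isSingular(fit, tol = 1e-4),
    converged = length(res$warnings) == 0, warnings = res$warnings,
    fit = fit, frame = frame, scalers = mf$scalers), class = "sm_model_fit")
}

#' Likelihood-ratio test between nested mixed models
#'
#' Both models must be (or are refit as) maximum-likelihood fits. The
#' statistic is `2 * (logLik_full - logLik_null)` clamped at zero; degrees
#' of freedom are the difference in total parameter count (fixed effects
#' plus variance-covariance parameters), so a focal term contributes its
#' fixed slope(s) and, when the null drops the focal random slope, the
#' slope's variance and covariance parameters too.
#'
#' @param full,null fitted `merMod` objects (refit to ML if REML).
#' @return list `df`, `chi2`, `p`.
#' @export
lrt <- function(full, null) {
  if (lme4::isREML(full)) full <- lme4::refitML(full)
  if (lme4::isREML(null)) null <- lme4::refitML(null)
  ll_f <- stats::logLik(full); ll_n <- stats::logLik(null)
  df <- attr(ll_f, "df") - attr(ll_n, "df")
  if (df < 0) stop("lrt: null model has more parameters than full model")
  if (!all(names(lme4::fixef(null)) %in% names(lme4::fixef(full))))
    stop("lrt: models are not nested")
  chi2 <- max(0, 2 * (as.numeric(ll_f) - as.numeric(ll_n)))
  list(df = df, chi2 = chi2,
       p = if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Variance inflation factors
#'
#' Generalized VIFs computed from the correlation matrix of the fixed-effect
#' model matrix (intercept removed), aggregating the columns of categorical
#' terms; for a continuous predictor this reduces to `1 / (1 - R^2)` from
#' regressing it on the remaining predictors. Perfectly collinear predictors
#' give `Inf`.
#'
#' @param x a fitted `merMod`/`lm`, or a numeric model matrix.
#' @param assign optional integer vector mapping columns of a matrix `x` to
#'   terms (as in `attr(model.matrix(...), "assign")`).
#' @return named numeric vector of (G)VIFs, one per term.
#' @export
vif_fixed <- function(x, assign = NULL) {
  if (inherits(x, "merMod")) {
    mm <- lme4::getME(x, "X")
    asn <- attr(mm, "assign")
    labs <- attr(stats::terms(x), "term.labels")
  } else if (inherits(x, "lm")) {
    mm <- stats::model.matrix(x)
    asn <- attr(mm, "assign")
    labs <- attr(stats::terms(x), "term.labels")
  } else {
    mm <- as.matrix(x)
    asn <- assign %||% seq_len(ncol(mm))
    labs <- colnames(mm) %||% paste0("V", seq_len(ncol(mm)))
  }
  drop_int <- asn != 0
  mm <- mm[, drop_int, drop = FALSE]
  asn <- asn[drop_int]
  terms_idx <- unique(asn)
  if (length(terms_idx) < 2) stop("vif: need at least two predictor terms")
  R <- stats::cor(mm)
  detR <- det(R)
  out <- vapply(terms_idx, function(tt) {
    sub <- asn == tt
    d1 <- det(R[sub, sub, drop = FALSE])
    d2 <- det(R[!sub, !sub, drop = FALSE])
    if (detR <= .Machine$double.eps) return(Inf)
    gvif <- d1 * d2 / detR
    # GVIF^(1/(2*df)) squared == VIF for a 1-df term; report VIF-scale
    gvif^(1 / length(which(sub)))
  }, numeric(1))
  names(out) <- labs[terms_idx]
  out
}

#' Run the full model suite
#'
#' Fits LMM1-LMM7 (or a subset) on an assembled dataset, returning the fits
#' and a Table-1-style report.
#'
#' @param data output of [build_dataset()].
#' @param specs list from [model_specs()]; default all seven.
#' @param models character vector of model names to fit.
#' @param ... passed to [fit_lmm()].
#' @return list with `fits` (named list; a failed model holds the error
#'   condition) and `report` (a `data.table` with one row per coefficient
#'   plus the per-model LRT, N individuals and n observations).
#' @export
run_suite <- function(data, specs = model_specs(),
                      models = names(specs), ...) {
  fits <- list()
  rows <- list()
  for (nm in models) {
    f <- tryCatch(fit_lmm(specs[[nm]], data, ...), error = function(e) e)
    fits[[nm]] <- f
    if (inherits(f, "error")) {
      rows[[nm]] <- data.table::data.table(
        model = nm, term = NA_character_, estimate = NA_real_, se = NA_real_,
        t = NA_real_, p = NA_real_, lrt_df = NA_real_, lrt_chi2 = NA_real_,
        lrt_p = NA_real_, max_vif = NA_real_, N = NA_integer_,
        n = NA_integer_, note = conditionMessage(f))
      next
    }
    tab <- data.table::copy(f$coefficients)
    if (!is.null(f$term_tests$reproductive_state)) {
      tt <- f$term_tests$reproductive_state
      tab <- rbind(tab, data.table::data.table(
        term = "reproductive_state (overall)", estimate = NA_real_,
        se = NA_real_, t = NA_real_, p = tt$p))
    }
    tab[, `:=`(model = nm, lrt_df = f$lrt$df, lrt_chi2 = f$lrt$chi2,
               lrt_p = f$lrt$p,
               max_vif = if (is.null(f$vif)) NA_real_ else max(f$vif),
               N = f$n_individuals, n = f$n_obs, note = NA_character_)]
    rows[[nm]] <- tab
  }
  report <- data.table::rbindlist(rows, use.names = TRUE, fill = TRUE)
  data.table::setcolorder(report, c("model", "term"))
  list(fits = fits, report = report[])
}

#' @export
print.sm_model_fit <- function(x, ...) {
  cat(sprintf("%s: n = %d observations, N = %d individuals%s\n", x$name,
              x$n_obs, x$n_individuals,
              if (x$singular) " (singular fit)" else ""))
  print(x$coefficients, digits = 3)
  cat(sprintf("LRT vs null: df = %d, chi2 = %.2f, p = %.3g\n",
              x$lrt$df, x$lrt$chi2, x$lrt$p))
  invisible(x)
}
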