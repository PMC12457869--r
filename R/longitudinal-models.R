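#' Random-intercept/random-slope linear mixed model for an EMA panel
#'
#' Fits \code{value ~ time (+ group + group:time) + (time | participant)}
#' by maximum likelihood: person-specific intercepts and linear slopes with
#' an unstructured 2x2 random-effects covariance, residuals independent
#' given the random effects.  Outliers are handled by the `robustness`
#' option: `"winsorized_input"` (the default) winsorizes the outcome at the
#' 5th/95th percentiles before fitting; `"huber"` runs iterative Huber
#' reweighting of residuals on top of the ML fit; `"none"` fits the raw
#' data.
#'
#' p-values for fixed effects use the Wald normal approximation, adequate
#' at the sample sizes these panels carry (hundreds of participants,
#' thousands of observations).
#'
#' @param panel EMA panel with `participant`, `time` (days) and `value`;
#'   a `group` column (0/1) is required when `include_group = TRUE`.
#' @param include_group add group main effect and group x time interaction.
#' @param robustness `"winsorized_input"`, `"huber"` or `"none"`.
#' @param estimation `"ML"` (default) or `"REML"`.
#' @param winsor_p quantile pair for the winsorized-input option.
#'
#' @return An `lmm_fit`: list with `fixed` (term, estimate, se, z, p),
#'   `tau00`, `tau11`, `tau01`, `sigma2`, `n_obs`, `n_participants`,
#'   `estimation`, `robustness`, `converged`, `singular`, and the
#'   underlying `lme4` fit as `model`.
#' @export
fit_random_slope_lmm <- function(panel, include_group = FALSE,
                                 robustness = c("winsorized_input", "huber",
                                                "none"),
                                 estimation = c("ML", "REML"),
                                 winsor_p = c(0.05, 0.95)) {
  robustness <- match.arg(robustness)
  estimation <- match.arg(estimation)
  d <- panel
  if (include_group && is.null(d$group))
    stop("panel must carry a group column for a group x time model")
  if (robustness == "winsorized_input")
    d$value <- as.numeric(winsorize(d$value, winsor_p[1], winsor_p[2]))
  form <- if (include_group)
    value ~ time * group + (time | participant)
  else
    value ~ time + (time | participant)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
  fit <- lme4::lmer(form, data = d, REML = identical(estimation, "REML"),
                    control = ctrl)
  if (robustness == "huber") fit <- huber_refit(fit, form, d, estimation)
  conv <- fit@optinfo$conv$opt == 0
  if (!conv)
    stop("mixed model failed to converge: ",
         paste(unlist(fit@optinfo$conv$lme4$messages), collapse = "; "))
  as_lmm_fit(fit, estimation, robustness)
}

# Iteratively reweighted fit: Huber weights on scaled residuals (k = 1.345).
huber_refit <- function(fit, form, d, estimation, k = 1.345, max_iter = 10L) {
  for (i in seq_len(max_iter)) {
    r <- stats::resid(fit)
    s <- stats::mad(r, center = 0)
    if (s == 0) break
    u <- abs(r / s)
    w <- ifelse(u <= k, 1, k / u)
    fit_new <- lme4::lmer(form, data = d, weights = w,
                          REML = identical(estimation, "REML"),
                          control = lme4::lmerControl(
                            check.conv.singular = "ignore"))
    delta <- max(abs(lme4::fixef(fit_new) - lme4::fixef(fit)))
    fit <- fit_new
    if (delta < 1e-6) break
  }
  fit
}

as_lmm_fit <- function(fit, estimation, robustness) {
  b <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- b / se
  vc <- lme4::VarCorr(fit)
  g <- vc[[1]]
  tau00 <- g[1, 1]
  tau11 <- if (nrow(g) > 1) g[2, 2] else 0
  tau01 <- if (nrow(g) > 1) g[1, 2] else 0
  structure(list(
    fixed = data.frame(term = names(b), estimate = as.numeric(b),
                       se = as.numeric(se), z = as.numeric(z),
                       p = 2 * stats::pnorm(-abs(as.numeric(z)))),
    tau00 = tau00, tau11 = tau11, tau01 = tau01,
    sigma2 = attr(vc, "sc")^2,
    n_obs = stats::nobs(fit),
    n_participants = lme4::ngrps(fit)[[1]],
    estimation = estimation, robustness = robustness,
    converged = TRUE,
    singular = lme4::isSingular(fit),
    logLik = as.numeric(stats::logLik(fit)),
    model = fit
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Linear mixed model (%s, robustness = %s): %d obs, %d participants\n",
              x$estimation, x$robustness, x$n_obs, x$n_participants))
  print(x$fixed, row.names = FALSE, digits = 4)
  cat(sprintf("tau00 = %.4g, tau11 = %.4g, tau01 = %.4g, sigma2 = %.4g%s\n",
              x$tau00, x$tau11, x$tau01, x$sigma2,
              if (x$singular) "  (singular random-effects covariance)" else ""))
  invisible(x)
}

#' Growth-model effect size (Feingold's d)
#'
#' Standardizes a growth-model slope coefficient by the raw-score SD at
#' baseline: \eqn{d = \beta_{time} \times duration / SD_{raw}}, i.e. the
#' model-implied change over the whole trial expressed in baseline SD
#' units.  The duration is an explicit argument so alternate conventions
#' (e.g. change per week) are one call away.
#'
#' @param beta_time slope per day.
#' @param duration_days trial length in days.
#' @param sd_raw baseline raw-score SD (> 0).
#' @return List of class `effect_size` with `d`, `beta_time`,
#'   `duration_days`, `sd_raw`.
#' @export
feingold_d <- function(beta_time, duration_days, sd_raw) {
  if (sd_raw <= 0) stop("sd_raw must be positive")
  structure(list(d = beta_time * duration_days / sd_raw,
                 beta_time = beta_time, duration_days = duration_days,
                 sd_raw = sd_raw), class = "effect_size")
}

#' ANCOVA-style group effect on questionnaire change
#'
#' OLS regression of T2 scores on T1 scores plus a group indicator; the
#' group coefficient is the adjusted group difference at T2, standardized
#' by a reference SD (by default the baseline SD of the pooled sample) to
#' give an effect size d.  Complete cases only (listwise; count attached).
#'
#' @param t1,t2 questionnaire scores at the two waves.
#' @param group arm labels (two levels; coerced to 0/1 factor codes).
#' @param sd_ref standardizer; defaults to `sd(t1)` over complete cases.
#' @param covariates optional data frame of additional adjustment terms
#'   (e.g. a sample indicator when trials are pooled).
#' @return List with `b`, `se`, `t`, `df`, `p`, `d`, `n`.
#' @export
ancova_group_effect <- function(t1, t2, group, sd_ref = NULL,
                                covariates = NULL) {
  g <- factor(group)
  if (nlevels(g) != 2) stop("group must have exactly two non-empty levels")
  d <- data.frame(t1 = t1, t2 = t2, group = g)
  if (!is.null(covariates)) d <- cbind(d, covariates)
  ok <- stats::complete.cases(d)
  d <- d[ok, , drop = FALSE]
  if (any(table(droplevels(d$group)) == 0)) stop("one group is empty")
  if (is.null(sd_ref)) sd_ref <- stats::sd(d$t1)
  fit <- stats::lm(t2 ~ ., data = d)
  sm <- summary(fit)$coefficients
  row <- grep("^group", rownames(sm))[1]
  b <- sm[row, "Estimate"]; se <- sm[row, "Std. Error"]
  list(b = b, se = se, t = sm[row, "t value"], df = fit$df.residual,
       p = sm[row, "Pr(>|t|)"], d = b / sd_ref, n = nrow(d),
       n_dropped = sum(!ok))
}

#' Longitudinal criterion validity of two change measures
#'
#' Tests whether residualized questionnaire change and the EMA slope each
#' predict depression improvement over repeated follow-up waves, with both
#' terms in the same mixed model.  Time is centered at the final follow-up
#' (so the main effects of the change scores are their association with
#' depression at endpoint), baseline depression enters as a covariate, and
#' both change x time interactions are estimated simultaneously with
#' participant random intercepts and slopes.
#'
#' By default the baseline wave is removed from the outcome vector when it
#' also serves as the covariate; `include_baseline_wave = TRUE` keeps it in
#' both roles.
#'
#' @param depression long table with `participant`, `time_frac` in `[0, 1]`
#'   (0 = baseline, 1 = final follow-up) and `value`.
#' @param changes table from [participant_changes()] with `retro_change`
#'   and `ema_slope`.
#' @param standardize z-score both change measures before fitting (so the
#'   two interaction coefficients are on comparable scales).
#' @param center `"final"` (default) or `"baseline"` time centering.
#' @param include_baseline_wave keep wave 0 in the outcome.
#' @param estimation `"ML"` or `"REML"`.
#' @return An `lmm_fit`; the two interaction rows are tagged
#'   `retro_change:time_c` and `ema_slope:time_c`.
#' @export
criterion_validity_longitudinal <- function(depression, changes,
                                            standardize = TRUE,
                                            center = c("final", "baseline"),
                                            include_baseline_wave = FALSE,
                                            estimation = c("ML", "REML")) {
  center <- match.arg(center)
  estimation <- match.arg(estimation)
  base <- depression[depression$time_frac == min(depression$time_frac),
                     c("participant", "value")]
  names(base)[2] <- "dep_baseline"
  d <- merge(depression, base, by = "participant")
  if (!include_baseline_wave)
    d <- d[d$time_frac > min(d$time_frac), , drop = FALSE]
  d <- merge(d, changes[c("participant", "retro_change", "ema_slope")],
             by = "participant")
  ok <- stats::complete.cases(d[c("retro_change", "ema_slope", "value")])
  n_excluded <- length(setdiff(unique(depression$participant),
                               unique(d$participant[ok])))
  d <- d[ok, , drop = FALSE]
  if (standardize) {
    d$retro_change <- as.numeric(scale(d$retro_change))
    d$ema_slope <- as.numeric(scale(d$ema_slope))
  }
  d$time_c <- if (center == "final") d$time_frac - max(d$time_frac)
    else d$time_frac - min(d$time_frac)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
  fit <- lme4::lmer(
    value ~ time_c * retro_change + time_c * ema_slope + dep_baseline +
      (time_c | participant),
    data = d, REML = identical(estimation, "REML"), control = ctrl)
  out <- as_lmm_fit(fit, estimation, "none")
  out$n_excluded <- n_excluded
  out
}

#' Pre/post criterion validity by OLS
#'
#' For designs with only two depression waves: OLS of post-test depression
#' on pre-test depression, residualized questionnaire change, and the EMA
#' slope (all entered simultaneously).  Complete cases, listwise.
#'
#' @param dep_t1,dep_t2 depression at pre- and post-test, aligned with
#'   `changes$participant`.
#' @param changes table with `retro_change` and `ema_slope`.
#' @return Data frame (term, estimate, se, t, p) with attributes `n`,
#'   `n_dropped` and `collinear` (condition-number flag).
#' @export
criterion_validity_prepost <- function(dep_t1, dep_t2, changes) {
  d <- data.frame(dep_t2 = dep_t2, dep_t1 = dep_t1,
                  retro_change = changes$retro_change,
                  ema_slope = changes$ema_slope)
  ok <- stats::complete.cases(d)
  d <- d[ok, , drop = FALSE]
  fit <- stats::lm(dep_t2 ~ dep_t1 + retro_change + ema_slope, data = d)
  X <- stats::model.matrix(fit)[, -1, drop = FALSE]
  kappa_x <- kappa(scale(X), exact = TRUE)
  sm <- summary(fit)$coefficients
  out <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                    t = sm[, 3], p = sm[, 4])
  rownames(out) <- NULL
  if (kappa_x > 30) warning("predictors are near-collinear (condition number ",
                            round(kappa_x, 1), ")")
  structure(out, n = nrow(d), n_dropped = sum(!ok),
            collinear = kappa_x > 30)
}

#' Paired pre/post effect
#'
#' Paired t test of T1 versus T2 scores with a standardized effect size;
#' the default standardizer is the baseline (T1) SD, consistent with the
#' growth-model effect-size convention, with pooled and difference-score
#' SDs selectable.
#'
#' @param t1,t2 paired scores.
#' @param standardizer `"baseline"`, `"pooled"` or `"difference"`.
#' @return List with `t`, `df`, `p`, `d`, `n`.
#' @export
paired_prepost_effect <- function(t1, t2,
                                  standardizer = c("baseline", "pooled",
                                                   "difference")) {
  standardizer <- match.arg(standardizer)
  ok <- is.finite(t1) & is.finite(t2)
  t1 <- t1[ok]; t2 <- t2[ok]
  if (stats::sd(t2 - t1) == 0) {
    if (all(t2 == t1))  # no change at all: a well-defined null result
      return(list(t = 0, df = length(t1) - 1, p = 1, d = 0, n = length(t1)))
    stop("zero variance of paired differences: degenerate input")
  }
  tt <- stats::t.test(t1, t2, paired = TRUE)
  sdv <- switch(standardizer,
                baseline = stats::sd(t1),
                pooled = sqrt((stats::var(t1) + stats::var(t2)) / 2),
                difference = stats::sd(t1 - t2))
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, d = mean(t1 - t2) / sdv, n = length(t1))
}
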