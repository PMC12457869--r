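#' Residualized change scores
#'
#' Residuals from the least-squares regression (with intercept) of T2
#' scores on T1 scores.  These capture change that is independent of
#' initial status and are robust to regression to the mean, unlike raw
#' difference scores.  Pairs with a missing value are dropped listwise; the
#' residuals are returned in input order with `NA` at dropped positions,
#' and the number of dropped pairs is attached as attribute `n_dropped`.
#'
#' @param t1,t2 numeric score vectors of equal length.
#' @return Residual vector (mean 0 over complete pairs, exactly orthogonal
#'   to `t1`).
#' @export
residualized_change <- function(t1, t2) {
  stopifnot(length(t1) == length(t2))
  ok <- is.finite(t1) & is.finite(t2)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  if (stats::var(t1[ok]) == 0) stop("T1 scores have zero variance")
  fit <- stats::lm(t2[ok] ~ t1[ok])
  out <- rep(NA_real_, length(t1))
  out[ok] <- stats::resid(fit)
  structure(out, n_dropped = sum(!ok))
}

#' OLS slope of one participant's momentary series
#'
#' Ordinary least-squares slope (with intercept) of value on fractional
#' day; day 0 is the first intervention day.  The slope is the
#' participant's estimated linear rate of change in EMA units per day.
#'
#' @param time fractional days.
#' @param value momentary values.
#' @param min_obs minimum number of observations (default 4); fewer returns
#'   `NA` so callers can flag and exclude the participant.
#' @return Slope, or `NA_real_` when under `min_obs`.
#' @export
person_ols_slope <- function(time, value, min_obs = 4L) {
  ok <- is.finite(time) & is.finite(value)
  time <- time[ok]; value <- value[ok]
  if (length(time) < min_obs) return(NA_real_)
  if (length(unique(time)) < 2)
    stop("all observations fall on a single time point")
  tc <- time - mean(time)
  sum(tc * (value - mean(value))) / sum(tc^2)
}

#' Per-participant EMA slopes for a whole panel
#'
#' @param panel EMA panel with `participant`, `time`, `value`.
#' @param min_obs minimum observations per participant.
#' @return Data frame with `participant`, `ema_slope` (NA below threshold),
#'   `n_ema_obs`.
#' @export
ema_slopes <- function(panel, min_obs = 4L) {
  parts <- split(panel, panel$participant, drop = TRUE)
  out <- data.frame(
    participant = names(parts),
    ema_slope = vapply(parts, function(d)
      person_ols_slope(d$time, d$value, min_obs = min_obs), numeric(1)),
    n_ema_obs = vapply(parts, nrow, integer(1))
  )
  rownames(out) <- NULL
  out
}

#' Windowed EMA means
#'
#' Mean momentary value within the first or last `k` days of the trial.
#' Windows are half-open in 0-based days: `first_k_days` covers days
#' `[0, k)`, `last_k_days` covers `[duration - k, duration)`.  Participants
#' with no observation in the window are absent from the output; their
#' count is attached as attribute `n_missing`.
#'
#' @param panel EMA panel with `participant`, `day`, `value`.
#' @param window `"first_k_days"` or `"last_k_days"`.
#' @param k window length in days (>= 1).
#' @param duration_days trial duration, required for `last_k_days`.
#' @return Data frame with `participant`, `window`, `k`, `value`.
#' @export
windowed_ema_mean <- function(panel, window = c("first_k_days", "last_k_days"),
                              k, duration_days = NULL) {
  window <- match.arg(window)
  if (k <= 0) stop("k must be at least 1")
  if (window == "first_k_days") {
    lo <- 0
  } else {
    if (is.null(duration_days))
      stop("duration_days is required for a last_k_days window")
    if (k > duration_days) stop("k exceeds the trial duration")
    lo <- duration_days - k
  }
  inwin <- panel$day >= lo & panel$day < lo + k
  sub <- panel[inwin, , drop = FALSE]
  means <- tapply(sub$value, sub$participant, mean)
  out <- data.frame(participant = names(means), window = window, k = k,
                    value = as.numeric(means))
  rownames(out) <- NULL
  n_missing <- length(unique(panel$participant)) - nrow(out)
  structure(out, n_missing = n_missing)
}

#' Winsorize a numeric vector
#'
#' Values below the `lower_p` empirical quantile are set to that quantile,
#' and values above the `upper_p` quantile likewise.  Quantiles use the
#' type-7 (linear interpolation) convention for reproducibility.  Order and
#' length are preserved; `NA`s pass through.  This is a single-pass
#' transform: re-applying it with the same *numeric* bounds is a no-op, but
#' re-estimating quantiles from already-winsorized data need not be.
#'
#' @param values numeric vector.
#' @param lower_p,upper_p quantile probabilities, `0 <= lower_p < upper_p <= 1`.
#' @param bounds optional numeric length-2; explicit cut values that
#'   override quantile estimation.
#' @return Winsorized vector with attribute `bounds` (the cut values used).
#' @export
winsorize <- function(values, lower_p = 0.05, upper_p = 0.95, bounds = NULL) {
  if (is.null(bounds)) {
    if (!(lower_p >= 0 && lower_p < upper_p && upper_p <= 1))
      stop("need 0 <= lower_p < upper_p <= 1")
    bounds <- stats::quantile(values, c(lower_p, upper_p), na.rm = TRUE,
                              type = 7, names = FALSE)
  }
  structure(pmin(pmax(values, bounds[1]), bounds[2]), bounds = bounds)
}

#' Compliance summary for an EMA panel
#'
#' Per-participant completion percentage against the scheduled number of
#' beeps (`duration_days * beeps_per_day`), the overall mean and SD, and a
#' weekly trend: the slope from regressing participant-week completion
#' proportions on the 0-based week index.  The trend is estimated by
#' default with a participant random intercept (a linear mixed model);
#' `trend = "ols"` pools all participant-weeks into one regression.
#'
#' @param panel EMA panel with `participant` and `day`.
#' @param design a [trial_design()] giving the schedule.
#' @param trend `"mixed"` or `"ols"`.
#' @return List with `per_participant` (participant, n_observed,
#'   n_scheduled, percent), `mean_percent`, `sd_percent`,
#'   `weekly_trend` (change in completion proportion per week), and
#'   `trend_p`.
#' @export
compliance_summary <- function(panel, design, trend = c("mixed", "ols")) {
  trend <- match.arg(trend)
  scheduled <- design$duration_days * design$beeps_per_day
  if (scheduled <= 0) stop("design schedules zero beeps")
  ids <- sort(unique(panel$participant))
  obs <- table(factor(panel$participant, levels = ids))
  per <- data.frame(participant = ids,
                    n_observed = as.integer(obs),
                    n_scheduled = scheduled,
                    percent = 100 * as.integer(obs) / scheduled)

  # participant-week completion proportions over full scheduled weeks
  n_weeks <- design$duration_days %/% 7L
  week_days <- pmin(7L, design$duration_days - 7L * (seq_len(n_weeks) - 1L))
  wk <- expand.grid(participant = ids, week = seq_len(n_weeks) - 1L,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cnt <- table(factor(panel$participant, levels = ids),
               factor(panel$day %/% 7L, levels = seq_len(n_weeks) - 1L))
  wk$prop <- as.vector(cnt) /
    (design$beeps_per_day * week_days[wk$week + 1L])

  if (trend == "mixed" && length(ids) > 2) {
    fit <- lme4::lmer(prop ~ week + (1 | participant), data = wk,
                      REML = FALSE,
                      control = lme4::lmerControl(
                        check.conv.singular = "ignore"))
    b <- lme4::fixef(fit)[["week"]]
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))[2]
  } else {
    fit <- stats::lm(prop ~ week, data = wk)
    b <- stats::coef(fit)[["week"]]
    se <- summary(fit)$coefficients["week", "Std. Error"]
  }
  z <- b / se
  list(per_participant = per,
       mean_percent = mean(per$percent),
       sd_percent = stats::sd(per$percent),
       weekly_trend = b,
       trend_p = 2 * stats::pnorm(-abs(z)))
}

#' Participant-level change-score table
#'
#' Joins residualized questionnaire change with EMA OLS slopes into the
#' table that feeds the validity analyses.
#'
#' @param waves questionnaire table (`participant`, `wave`, item columns).
#' @param panel EMA panel.
#' @param min_obs minimum EMA observations for a slope.
#' @return Data frame with `participant`, `retro_t1`, `retro_t2`,
#'   `retro_change`, `ema_slope`, `n_ema_obs`.
#' @export
participant_changes <- function(waves, panel, min_obs = 4L) {
  scores <- questionnaire_totals(waves)
  wide <- stats::reshape(scores, idvar = "participant", timevar = "wave",
                         direction = "wide")
  names(wide) <- sub("^total\\.", "retro_", tolower(names(wide)))
  wide$retro_change <- as.numeric(residualized_change(wide$retro_t1,
                                                      wide$retro_t2))
  slopes <- ema_slopes(panel, min_obs = min_obs)
  out <- merge(wide, slopes, by = "participant", all.x = TRUE)
  out[order(out$participant), , drop = FALSE]
}

#' Total questionnaire scores per participant and wave
#'
#' @param waves questionnaire table with `participant`, `wave` and
#'   `item_*` columns; rows with any missing item are dropped listwise.
#' @return Data frame with `participant`, `wave`, `total`.
#' @export
questionnaire_totals <- function(waves) {
  item_cols <- grep("^item_", names(waves), value = TRUE)
  if (length(item_cols) == 0) stop("no item_* columns found")
  complete <- stats::complete.cases(waves[item_cols])
  w <- waves[complete, , drop = FALSE]
  data.frame(participant = w$participant, wave = w$wave,
             total = rowSums(w[item_cols]))
}
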