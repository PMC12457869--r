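#' Trial design for a synthetic EMA intervention study
#'
#' Describes the measurement schedule of a trial: how many participants and
#' arms, how long the EMA period runs, how many prompts ("beeps") are
#' scheduled per day, the response scale of the momentary item, the trait
#' questionnaire length and Likert range, and how many depression waves are
#' collected.
#'
#' Two stock designs bracket the studies this package emulates: a 21-day,
#' 3-beeps-per-day trial with a 0-100 momentary scale and a 13-item 0-4
#' questionnaire (see [care_design()]), and a 28-day, 4-beeps-per-day trial
#' on a 1-7 scale with a 15-item questionnaire (see [hmp_design()]).
#'
#' @param n_participants number of participants.
#' @param n_arms 1 (single-arm) or 2 (intervention vs control).
#' @param duration_days length of the EMA period in days (>= 7).
#' @param beeps_per_day scheduled prompts per day (>= 1).
#' @param ema_scale numeric length-2, lower and upper bound of the momentary
#'   item, strictly ordered.
#' @param n_items_t number of trait-questionnaire items (>= 2).
#' @param item_scale integer length-2 Likert bounds, strictly ordered.
#' @param depression_waves number of depression assessment waves (2 or 4).
#'
#' @return An object of class `trial_design` (a list of the above).
#' @export
trial_design <- function(n_participants, n_arms = 2, duration_days = 21,
                         beeps_per_day = 3, ema_scale = c(0, 100),
                         n_items_t = 13, item_scale = c(0, 4),
                         depression_waves = 4) {
  stopifnot(n_participants >= 1, n_arms %in% c(1, 2))
  if (duration_days < 7) stop("duration_days must be at least 7")
  if (beeps_per_day < 1) stop("beeps_per_day must be at least 1")
  if (length(ema_scale) != 2 || ema_scale[1] >= ema_scale[2])
    stop("ema_scale bounds must be strictly ordered (lower, upper)")
  if (length(item_scale) != 2 || item_scale[1] >= item_scale[2])
    stop("item_scale bounds must be strictly ordered (lower, upper)")
  if (n_items_t < 2) stop("n_items_t must be at least 2")
  if (!depression_waves %in% c(2, 4))
    stop("depression_waves must be 2 or 4")
  structure(list(
    n_participants = as.integer(n_participants),
    n_arms = as.integer(n_arms),
    duration_days = as.integer(duration_days),
    beeps_per_day = as.integer(beeps_per_day),
    ema_scale = as.numeric(ema_scale),
    n_items_t = as.integer(n_items_t),
    item_scale = as.integer(item_scale),
    depression_waves = as.integer(depression_waves)
  ), class = "trial_design")
}

#' @rdname trial_design
#' @export
care_design <- function(n_participants = 320, n_arms = 2) {
  trial_design(n_participants, n_arms, duration_days = 21, beeps_per_day = 3,
               ema_scale = c(0, 100), n_items_t = 13, item_scale = c(0, 4),
               depression_waves = 4)
}

#' @rdname trial_design
#' @export
hmp_design <- function(n_participants = 92, n_arms = 1) {
  trial_design(n_participants, n_arms, duration_days = 28, beeps_per_day = 4,
               ema_scale = c(1, 7), n_items_t = 15, item_scale = c(0, 4),
               depression_waves = 2)
}

#' Ground-truth generating parameters for a synthetic trial
#'
#' The momentary series follows a linear growth model
#' \deqn{y_{ij} = (\gamma_{00} + \gamma_{01} g_i + u_{0i})
#'   + (\gamma_{10} + \gamma_{11} g_i + u_{1i}) t_{ij} + e_{ij}}
#' with \eqn{g_i} a 0/1 arm indicator, person effects \eqn{(u_{0i}, u_{1i})}
#' bivariate normal with variances `tau00`, `tau11` and covariance `tau01`,
#' and residuals \eqn{e_{ij} \sim N(0, \sigma^2)} independent given the
#' random effects.  Values are clipped to the design's scale bounds after
#' noise, so boundary pile-up can occur just as on a real slider scale.
#'
#' Questionnaire items are congeneric: item score = `trait_loading` * latent
#' trait + normal noise with SD `trait_noise_sd`, rounded and clipped to the
#' Likert range.  The latent trait at the second wave equals the trait at
#' baseline plus a true change component whose correlation with the
#' participant's true EMA slope is `change_cor` -- this is the knob that
#' controls how strongly "questionnaire change" and "momentary change" agree
#' at the level of truth, before any measurement error.
#'
#' Each scheduled beep is observed independently with probability
#' `compliance_base - compliance_weekly_decline * week` (week 0-based),
#' i.e. missingness is completely at random within week strata.
#'
#' Depression improvement per unit of study time loads on the true trait
#' change (`dep_effect_retro`) and the true EMA slope (`dep_effect_ema`).
#'
#' @param gamma00,gamma10 fixed intercept (EMA units) and slope (per day).
#' @param gamma01,gamma11 arm effects on intercept and slope.
#' @param tau00,tau11,tau01 random intercept/slope variances and covariance;
#'   the implied 2x2 matrix must be positive semidefinite.
#' @param sigma2 within-person residual variance (>= 0).
#' @param trait_loading,trait_noise_sd congeneric item model parameters.
#' @param trait_mean,trait_sd mean and SD of the latent baseline trait.
#' @param trait_change_mean,trait_change_sd mean and SD of true trait change.
#' @param change_cor correlation in (-1, 1) between true trait change and the
#'   person's true EMA slope.
#' @param trait_state_cor correlation in (-1, 1) between the latent baseline
#'   trait and the person's true EMA intercept -- the shared variance that
#'   produces the single-time-point convergence between questionnaire scores
#'   and momentary means.
#' @param compliance_base probability in (0, 1] that a beep in week 0 is
#'   answered.
#' @param compliance_weekly_decline drop in that probability per week, in
#'   probability points.
#' @param dep_effect_retro,dep_effect_ema loadings of true trait change and
#'   true EMA slope on depression improvement.
#' @param dep_base_mean,dep_base_sd,dep_noise_sd,dep_slope_noise_sd scale of
#'   the generic continuous depression outcome.
#'
#' @return An object of class `truth_params`.
#' @export
truth_params <- function(gamma00 = 40, gamma10 = -0.3, gamma01 = 0,
                         gamma11 = -0.2, tau00 = 225, tau11 = 0.16,
                         tau01 = -1.2, sigma2 = 300,
                         trait_loading = 0.8, trait_noise_sd = 0.55,
                         trait_mean = 2, trait_sd = 0.8,
                         trait_change_mean = -0.25, trait_change_sd = 0.6,
                         change_cor = 0.4, trait_state_cor = 0.5,
                         compliance_base = 0.78,
                         compliance_weekly_decline = 0.03,
                         dep_effect_retro = 0.3, dep_effect_ema = 0.3,
                         dep_base_mean = 10, dep_base_sd = 3,
                         dep_noise_sd = 1.5, dep_slope_noise_sd = 1) {
  stopifnot(tau00 >= 0, tau11 >= 0, sigma2 >= 0)
  if (abs(tau01) > sqrt(tau00 * tau11) + 1e-12)
    stop("|tau01| must not exceed sqrt(tau00 * tau11)")
  if (compliance_base <= 0 || compliance_base > 1)
    stop("compliance_base must be in (0, 1]")
  if (abs(change_cor) >= 1) stop("change_cor must be in (-1, 1)")
  if (abs(trait_state_cor) >= 1) stop("trait_state_cor must be in (-1, 1)")
  structure(as.list(environment()), class = "truth_params")
}

# Scheduled measurement times as fractional days: day + beep/beeps_per_day,
# day and beep both 0-based. The apps' clock times are not modeled.
schedule_grid <- function(design) {
  days <- rep(seq_len(design$duration_days) - 1L, each = design$beeps_per_day)
  beeps <- rep(seq_len(design$beeps_per_day) - 1L, times = design$duration_days)
  data.frame(day = days, beep = beeps,
             time = days + beeps / design$beeps_per_day)
}

#' Simulate a complete synthetic trial
#'
#' Generates the four tables the analysis pipeline consumes: a long EMA
#' panel, the two questionnaire waves, a multi-wave depression table, and a
#' ground-truth record per participant (true intercepts and slopes, true
#' latent traits) against which parameter recovery can be asserted.
#'
#' @param design a [trial_design()].
#' @param truth a [truth_params()].
#' @param seed integer seed; identical seeds give identical output.
#'
#' @return A list of class `sim_trial` with elements `ema` (participant,
#'   day, beep, time, value), `waves` (participant, wave, item_1..item_k),
#'   `depression` (participant, wave, time_frac, value), `truth`
#'   (participant, group, true_intercept, true_slope, true_trait_t1,
#'   true_trait_t2), and the `design`/`params`/`seed` used.
#' @export
simulate_trial <- function(design, truth, seed) {
  stopifnot(inherits(design, "trial_design"), inherits(truth, "truth_params"))
  n <- design$n_participants
  final_week <- (design$duration_days - 1L) %/% 7L
  p_final <- truth$compliance_base -
    truth$compliance_weekly_decline * final_week
  if (p_final < 0)
    stop(sprintf("compliance probability falls below 0 in week %d", final_week))

  set.seed(as.integer(seed))
  id <- sprintf("P%04d", seq_len(n))
  group <- if (design$n_arms == 2) rep_len(c(0L, 1L), n) else rep(1L, n)

  # person effects: bivariate normal via Cholesky-style construction
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  u0 <- sqrt(truth$tau00) * z1
  if (truth$tau00 > 0 && truth$tau11 > 0) {
    rho <- truth$tau01 / sqrt(truth$tau00 * truth$tau11)
    u1 <- sqrt(truth$tau11) * (rho * z1 + sqrt(1 - rho^2) * z2)
  } else {
    u1 <- sqrt(truth$tau11) * z2
  }
  intercept_i <- truth$gamma00 + truth$gamma01 * group + u0
  slope_i <- truth$gamma10 + truth$gamma11 * group + u1

  grid <- schedule_grid(design)
  m <- nrow(grid)
  panel <- data.frame(
    participant = rep(id, each = m),
    day = rep(grid$day, times = n),
    beep = rep(grid$beep, times = n),
    time = rep(grid$time, times = n)
  )
  mu <- rep(intercept_i, each = m) + rep(slope_i, each = m) * panel$time
  y <- mu + stats::rnorm(n * m, sd = sqrt(truth$sigma2))
  panel$value <- pmin(pmax(y, design$ema_scale[1]), design$ema_scale[2])
  p_obs <- truth$compliance_base -
    truth$compliance_weekly_decline * (panel$day %/% 7L)
  keep <- stats::runif(n * m) < p_obs
  panel <- panel[keep, , drop = FALSE]
  rownames(panel) <- NULL

  # latent traits: baseline trait shares variance with the true EMA level,
  # true change correlates with the standardized true slope
  int_sd <- stats::sd(intercept_i)
  int_std <- if (is.na(int_sd) || int_sd == 0) rep(0, n) else
    (intercept_i - mean(intercept_i)) / int_sd
  trait_t1 <- truth$trait_mean + truth$trait_sd *
    (truth$trait_state_cor * int_std +
       sqrt(1 - truth$trait_state_cor^2) * stats::rnorm(n))
  slope_sd <- stats::sd(slope_i)
  slope_std <- if (is.na(slope_sd) || slope_sd == 0) rep(0, n) else
    (slope_i - mean(slope_i)) / slope_sd
  delta <- truth$trait_change_mean + truth$trait_change_sd *
    (truth$change_cor * slope_std +
       sqrt(1 - truth$change_cor^2) * stats::rnorm(n))
  trait_t2 <- trait_t1 + delta

  waves <- rbind(
    congeneric_items(trait_t1, design, truth, wave = "T1", id = id),
    congeneric_items(trait_t2, design, truth, wave = "T2", id = id)
  )

  # depression: improvement per unit study-time loads on both true changes
  W <- design$depression_waves
  time_frac <- seq(0, 1, length.out = W)
  dep0 <- truth$dep_base_mean + truth$dep_base_sd * stats::rnorm(n)
  improve <- truth$dep_effect_retro * delta +
    truth$dep_effect_ema * slope_i +
    truth$dep_slope_noise_sd * stats::rnorm(n)
  depression <- data.frame(
    participant = rep(id, each = W),
    wave = rep(seq_len(W) - 1L, times = n),
    time_frac = rep(time_frac, times = n)
  )
  depression$value <- rep(dep0, each = W) +
    rep(improve, each = W) * depression$time_frac +
    truth$dep_noise_sd * stats::rnorm(n * W)

  truth_rec <- data.frame(
    participant = id, group = group,
    true_intercept = intercept_i, true_slope = slope_i,
    true_trait_t1 = trait_t1, true_trait_t2 = trait_t2
  )
  structure(list(ema = panel, waves = waves, depression = depression,
                 truth = truth_rec, design = design, params = truth,
                 seed = as.integer(seed)),
            class = "sim_trial")
}

congeneric_items <- function(latent, design, truth, wave, id) {
  n <- length(latent); k <- design$n_items_t
  raw <- truth$trait_loading * rep(latent, each = k) +
    truth$trait_noise_sd * stats::rnorm(n * k)
  scored <- pmin(pmax(round(raw), design$item_scale[1]), design$item_scale[2])
  items <- matrix(scored, nrow = n, byrow = TRUE,
                  dimnames = list(NULL, paste0("item_", seq_len(k))))
  cbind(data.frame(participant = id, wave = wave), as.data.frame(items))
}

#' Design-expected reliability of person-level OLS slopes
#'
#' Closed-form expectation of the multilevel slope reliability
#' \eqn{\lambda = \tau_{11} / (\tau_{11} + \sigma^2 / SS_t)}, where
#' \eqn{SS_t} is the expected centered sum of squares of a participant's
#' observed measurement times.  Under full compliance this is exact (every
#' participant sees the same grid); under partial compliance the expected
#' sum of squares is approximated by the simple-random-sample identity
#' \eqn{E[SS_t] = (pN - 1)\,\mathrm{Var}(t)} over the scheduled grid.
#'
#' Serves as the analytic oracle against which split-half and
#' multilevel-model reliability estimates on simulated data are checked.
#'
#' @param design a [trial_design()].
#' @param truth a [truth_params()]; only `tau11` and `sigma2` are used.
#' @param compliance probability in (0, 1] that a scheduled beep is observed.
#'
#' @return Expected slope reliability in `[0, 1]`.
#' @export
expected_slope_reliability <- function(design, truth, compliance = 1) {
  stopifnot(inherits(design, "trial_design"), inherits(truth, "truth_params"))
  if (truth$tau11 + truth$sigma2 <= 0)
    stop("tau11 + sigma2 must be positive")
  if (compliance <= 0 || compliance > 1)
    stop("compliance must be in (0, 1]")
  t <- schedule_grid(design)$time
  if (stats::var(t) == 0) stop("zero variance of observed times")
  ss <- (compliance * length(t) - 1) * stats::var(t)
  if (ss <= 0) stop("expected time sum of squares is not positive")
  if (truth$tau11 == 0) return(0)
  if (truth$sigma2 == 0) return(1)
  truth$tau11 / (truth$tau11 + truth$sigma2 / ss)
}

#' Write the four tables of a simulated trial as delimited text
#'
#' @param trial a `sim_trial` from [simulate_trial()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the four file paths.
#' @export
write_sim_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "sim_trial"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("ema.csv", "waves.csv", "depression.csv",
                            "truth.csv"))
  utils::write.csv(trial$ema, paths[1], row.names = FALSE)
  utils::write.csv(trial$waves, paths[2], row.names = FALSE)
  utils::write.csv(trial$depression, paths[3], row.names = FALSE)
  utils::write.csv(trial$truth, paths[4], row.names = FALSE)
  invisible(paths)
}
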