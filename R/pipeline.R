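#' Read an EMA panel from delimited text
#'
#' Strict schema: columns `participant` (character), `day` (non-negative
#' integer), `beep` (non-negative integer), `value` (numeric within the
#' declared scale bounds), and optionally `time` (fractional day; rebuilt
#' as `day + beep / beeps_per_day` when absent).  Duplicate
#' (participant, day, beep) rows and out-of-bounds values are rejected with
#' row numbers.
#'
#' @param path CSV file.
#' @param ema_scale numeric length-2 declared bounds.
#' @param beeps_per_day used to reconstruct fractional time when no `time`
#'   column is present.
#' @return EMA panel data frame.
#' @export
read_ema_table <- function(path, ema_scale = c(0, 100), beeps_per_day = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0) stop("EMA table ", path, " is empty")
  need <- c("participant", "day", "beep", "value")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0)
    stop("EMA table ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  d$participant <- as.character(d$participant)
  if (any(d$day < 0) || any(d$day != floor(d$day)))
    stop("day must be a non-negative integer; first bad row: ",
         which(d$day < 0 | d$day != floor(d$day))[1])
  if (any(d$beep < 0) || any(d$beep != floor(d$beep)))
    stop("beep must be a non-negative integer; first bad row: ",
         which(d$beep < 0 | d$beep != floor(d$beep))[1])
  bad <- which(d$value < ema_scale[1] | d$value > ema_scale[2])
  if (length(bad) > 0)
    stop("value outside declared scale [", ema_scale[1], ", ", ema_scale[2],
         "] in row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  key <- paste(d$participant, d$day, d$beep)
  if (anyDuplicated(key))
    stop("duplicate (participant, day, beep) rows, e.g. row ",
         which(duplicated(key))[1])
  if (is.null(d$time)) {
    if (is.null(beeps_per_day))
      stop("no time column; supply beeps_per_day to reconstruct it")
    d$time <- d$day + d$beep / beeps_per_day
  }
  d
}

#' Read a questionnaire wave table
#'
#' Schema: `participant`, `wave` in {T1, T2, FU6, FU12}, and `item_*`
#' integer columns.
#'
#' @param path CSV file.
#' @return Questionnaire data frame.
#' @export
read_wave_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0) stop("wave table ", path, " is empty")
  if (!all(c("participant", "wave") %in% names(d)))
    stop("wave table ", path, " needs participant and wave columns")
  bad <- which(!d$wave %in% c("T1", "T2", "FU6", "FU12"))
  if (length(bad) > 0)
    stop("unknown wave label in row(s): ", paste(utils::head(bad, 5),
                                                 collapse = ", "))
  if (length(grep("^item_", names(d))) == 0)
    stop("wave table ", path, " has no item_* columns")
  d$participant <- as.character(d$participant)
  d
}

#' Read a multi-wave depression table
#'
#' Schema: `participant`, `wave` (0-based integer), `time_frac` in
#' `[0, 1]`, `value`.
#'
#' @param path CSV file.
#' @return Depression data frame.
#' @export
read_depression_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0) stop("depression table ", path, " is empty")
  need <- c("participant", "wave", "time_frac", "value")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0)
    stop("depression table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  if (any(d$time_frac < 0 | d$time_frac > 1))
    stop("time_frac must lie in [0, 1]; first bad row: ",
         which(d$time_frac < 0 | d$time_frac > 1)[1])
  d$participant <- as.character(d$participant)
  d
}

#' Study configuration
#'
#' Either a synthetic block (design + truth parameters) or paths to the
#' three input tables, plus the analysis knobs: windowed-mean width,
#' winsorization quantiles, minimum observations for slopes, robustness
#' and estimation flags, time centering, and all seeds.
#'
#' @param synthetic list with `design` ([trial_design()]), `truth`
#'   ([truth_params()]); mutually exclusive with `paths`.
#' @param paths list with `ema`, `waves`, `depression` file paths.
#' @param window_k windowed-mean width in days.
#' @param winsor_p quantile pair for winsorization.
#' @param min_obs minimum EMA observations for slope inclusion.
#' @param split_seed seed for the random split-half partition.
#' @param sim_seed seed for the synthetic generator.
#' @param n_splits random splits to average in split-half reliability.
#' @param robustness,estimation,center model flags (see
#'   [fit_random_slope_lmm()], [criterion_validity_longitudinal()]).
#' @return List of class `study_config`.
#' @export
study_config <- function(synthetic = NULL, paths = NULL, window_k = 3L,
                         winsor_p = c(0.05, 0.95), min_obs = 4L,
                         split_seed = 1L, sim_seed = 1L, n_splits = 1L,
                         robustness = "winsorized_input", estimation = "ML",
                         center = "final") {
  if (is.null(synthetic) && is.null(paths))
    stop("config needs either a synthetic block or input paths")
  structure(list(synthetic = synthetic, paths = paths,
                 window_k = as.integer(window_k), winsor_p = winsor_p,
                 min_obs = as.integer(min_obs),
                 split_seed = as.integer(split_seed),
                 sim_seed = as.integer(sim_seed),
                 n_splits = as.integer(n_splits),
                 robustness = robustness, estimation = estimation,
                 center = center), class = "study_config")
}

#' Read a study configuration from a flat YAML file
#'
#' Recognized keys mirror the [study_config()] arguments; a `synthetic:`
#' block holds `design:` and `truth:` sub-blocks whose keys are passed to
#' [trial_design()] and [truth_params()].
#'
#' @param path YAML file.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  synthetic <- NULL
  if (!is.null(y$synthetic)) {
    des <- y$synthetic$design
    if (!is.null(des$ema_scale)) des$ema_scale <- as.numeric(des$ema_scale)
    if (!is.null(des$item_scale)) des$item_scale <- as.integer(des$item_scale)
    synthetic <- list(design = do.call(trial_design, des),
                      truth = do.call(truth_params,
                                      as.list(y$synthetic$truth)))
  }
  args <- y[setdiff(names(y), "synthetic")]
  do.call(study_config, c(list(synthetic = synthetic), args))
}

#' Run the four-criterion evaluation pipeline
#'
#' Executes, in order: (1) reliability -- internal consistency at both
#' waves, residualized-change reliability, split-half reliability of EMA
#' means and slopes (raw and Spearman-Brown adjusted), and multilevel-model
#' slope reliability; (2) convergent validity -- correlations between
#' questionnaire scores and windowed EMA means at each wave, and between
#' the two change scores; (3) sensitivity to change -- the ANCOVA-style
#' group effect on questionnaire change and the group x time (or time)
#' effect in the EMA mixed model, both as growth-model effect sizes;
#' (4) criterion validity -- the longitudinal (4-wave) or pre/post
#' (2-wave) depression models with both change measures entered together.
#' Analyses that the design cannot support (no control arm, too few
#' depression waves) are reported as skipped with a reason.
#'
#' Identical configuration and seeds give identical reports.
#'
#' @param config a [study_config()].
#' @return A list of class `study_report` with elements `reliability`,
#'   `convergence`, `effects`, `criterion`, `compliance`, `meta`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "study_config"))
  if (!is.null(config$synthetic)) {
    trial <- simulate_trial(config$synthetic$design, config$synthetic$truth,
                            seed = config$sim_seed)
    design <- config$synthetic$design
    ema <- trial$ema; waves <- trial$waves; depression <- trial$depression
  } else {
    p <- config$paths
    design <- p$design
    if (is.null(design)) stop("paths config must include a trial design")
    ema <- read_ema_table(p$ema, ema_scale = design$ema_scale,
                          beeps_per_day = design$beeps_per_day)
    waves <- read_wave_table(p$waves)
    depression <- read_depression_table(p$depression)
  }

  # criterion 1: reliability
  t1_items <- waves[waves$wave == "T1", grep("^item_", names(waves))]
  t2_items <- waves[waves$wave == "T2", grep("^item_", names(waves))]
  alpha_t1 <- cronbach_alpha(t1_items)
  alpha_t2 <- cronbach_alpha(t2_items)
  totals <- questionnaire_totals(waves)
  tw <- stats::reshape(totals, idvar = "participant", timevar = "wave",
                       direction = "wide")
  r12 <- stats::cor(tw$total.T1, tw$total.T2, use = "complete.obs")
  rel_resid <- residualized_change_reliability(
    min(as.numeric(alpha_t1), 1), min(as.numeric(alpha_t2), 1), r12)
  sh_mean <- split_half_reliability(ema, "mean", seed = config$split_seed,
                                    n_splits = config$n_splits)
  sh_slope <- split_half_reliability(ema, "slope", seed = config$split_seed,
                                     min_obs = config$min_obs,
                                     n_splits = config$n_splits)
  lmm_ema <- fit_random_slope_lmm(ema, include_group = FALSE,
                                  robustness = config$robustness,
                                  estimation = config$estimation,
                                  winsor_p = config$winsor_p)
  mlm_rel <- mlm_slope_reliability(
    lmm_ema, time_ss_by_participant(ema, min_obs = config$min_obs))
  reliability <- data.frame(
    method = c("alpha_t1", "alpha_t2", "residualized_change",
               "split_half_mean", "split_half_slope", "mlm_slope"),
    value_raw = c(as.numeric(alpha_t1), as.numeric(alpha_t2), rel_resid,
                  sh_mean$value_raw, sh_slope$value_raw, mlm_rel$value_raw),
    value_sb = c(NA, NA, NA, sh_mean$value_sb, sh_slope$value_sb, NA),
    n_units = c(attr(alpha_t1, "n_units"), attr(alpha_t2, "n_units"),
                sum(stats::complete.cases(tw)), sh_mean$n_units,
                sh_slope$n_units, mlm_rel$n_units),
    seed = c(NA, NA, NA, config$split_seed, config$split_seed, NA)
  )

  # criterion 2: convergence of the two measurement streams
  changes <- participant_changes(waves, ema, min_obs = config$min_obs)
  first_win <- windowed_ema_mean(ema, "first_k_days", k = config$window_k)
  last_win <- windowed_ema_mean(ema, "last_k_days", k = config$window_k,
                                duration_days = design$duration_days)
  conv <- rbind(
    cor_row("t1_vs_first_window", changes, first_win, "retro_t1"),
    cor_row("t2_vs_last_window", changes, last_win, "retro_t2"),
    {
      cc <- changes[stats::complete.cases(
        changes[c("retro_change", "ema_slope")]), ]
      rc <- as.numeric(winsorize(cc$retro_change, config$winsor_p[1],
                                 config$winsor_p[2]))
      es <- as.numeric(winsorize(cc$ema_slope, config$winsor_p[1],
                                 config$winsor_p[2]))
      ct <- stats::cor.test(rc, es)
      data.frame(comparison = "change_vs_slope", r = unname(ct$estimate),
                 n = nrow(cc), p = ct$p.value)
    })

  # criterion 3: sensitivity to change
  has_groups <- !is.null(config$synthetic) &&
    config$synthetic$design$n_arms == 2
  if (has_groups) {
    grp <- trial$truth[c("participant", "group")]
    tw2 <- merge(tw, grp, by = "participant")
    sd_ref <- stats::sd(tw2$total.T1, na.rm = TRUE)
    anc <- ancova_group_effect(tw2$total.T1, tw2$total.T2, tw2$group,
                               sd_ref = sd_ref)
    ema_g <- merge(ema, grp, by = "participant")
    lmm_g <- fit_random_slope_lmm(ema_g, include_group = TRUE,
                                  robustness = config$robustness,
                                  estimation = config$estimation,
                                  winsor_p = config$winsor_p)
    b_int <- lmm_g$fixed[lmm_g$fixed$term == "time:group", ]
    d_ema <- feingold_d(b_int$estimate, design$duration_days,
                        sd_ref_ema(ema))
    effects <- data.frame(
      measure = c("questionnaire_ancova", "ema_group_by_time"),
      b = c(anc$b, b_int$estimate), se = c(anc$se, b_int$se),
      p = c(anc$p, b_int$p), d = c(anc$d, d_ema$d))
    skipped_effects <- NULL
  } else {
    pp <- paired_prepost_effect(tw$total.T1, tw$total.T2)
    b_time <- lmm_ema$fixed[lmm_ema$fixed$term == "time", ]
    d_ema <- feingold_d(b_time$estimate, design$duration_days,
                        sd_ref_ema(ema))
    effects <- data.frame(
      measure = c("questionnaire_prepost", "ema_time"),
      b = c(mean(tw$total.T2 - tw$total.T1, na.rm = TRUE), b_time$estimate),
      se = c(NA, b_time$se), p = c(pp$p, b_time$p), d = c(pp$d, d_ema$d))
    skipped_effects <- "no control arm: within-group change reported instead of a group comparison"
  }

  # criterion 4: incremental criterion validity
  waves_n <- length(unique(depression$wave))
  dep_wide <- stats::reshape(depression[c("participant", "wave", "value")],
                             idvar = "participant", timevar = "wave",
                             direction = "wide")
  chg_w <- changes
  chg_w$retro_change <- as.numeric(winsorize(chg_w$retro_change,
                                             config$winsor_p[1],
                                             config$winsor_p[2]))
  chg_w$ema_slope <- as.numeric(winsorize(chg_w$ema_slope,
                                          config$winsor_p[1],
                                          config$winsor_p[2]))
  if (waves_n >= 3) {
    cv <- criterion_validity_longitudinal(depression, chg_w,
                                          center = config$center,
                                          estimation = config$estimation)
    rows <- cv$fixed[grep(":", cv$fixed$term), ]
    criterion <- data.frame(model = "longitudinal_lmm", term = rows$term,
                            estimate = rows$estimate, se = rows$se,
                            p = rows$p)
  } else {
    m <- merge(dep_wide, chg_w, by = "participant")
    cv <- criterion_validity_prepost(m$value.0, m$value.1, m)
    rows <- cv[cv$term %in% c("retro_change", "ema_slope"), ]
    criterion <- data.frame(model = "prepost_ols", term = rows$term,
                            estimate = rows$estimate, se = rows$se,
                            p = rows$p)
  }

  compliance <- compliance_summary(ema, design)
  structure(list(
    reliability = reliability, convergence = conv, effects = effects,
    criterion = criterion, compliance = compliance, changes = changes,
    skipped = skipped_effects,
    meta = list(sim_seed = config$sim_seed, split_seed = config$split_seed,
                n_splits = config$n_splits, robustness = config$robustness,
                estimation = config$estimation, window_k = config$window_k,
                winsor_p = config$winsor_p, min_obs = config$min_obs)
  ), class = "study_report")
}

cor_row <- function(label, changes, win, score_col) {
  m <- merge(changes[c("participant", score_col)], win, by = "participant")
  m <- m[stats::complete.cases(m[c(score_col, "value")]), ]
  ct <- stats::cor.test(m[[score_col]], m$value)
  data.frame(comparison = label, r = unname(ct$estimate), n = nrow(m),
             p = ct$p.value)
}

# baseline raw SD of the momentary outcome: SD of day-0 observations
sd_ref_ema <- function(ema) {
  s <- stats::sd(ema$value[ema$day == min(ema$day)])
  if (is.na(s) || s == 0) stats::sd(ema$value) else s
}

#' Write a study report as delimited tables plus a text summary
#'
#' @param report a `study_report` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- c("reliability", "convergence", "effects", "criterion")
  paths <- character(0)
  for (t in tabs) {
    p <- file.path(dir, paste0(t, ".csv"))
    utils::write.csv(report[[t]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "compliance.csv")
  utils::write.csv(report$compliance$per_participant, p, row.names = FALSE)
  paths <- c(paths, p)
  con <- file.path(dir, "summary.txt")
  lines <- c(
    "Four-criterion evaluation report",
    sprintf("seeds: sim=%d split=%d; robustness=%s; estimation=%s",
            report$meta$sim_seed, report$meta$split_seed,
            report$meta$robustness, report$meta$estimation),
    sprintf("compliance: mean %.1f%% (SD %.1f%%), weekly trend %+.4f",
            report$compliance$mean_percent, report$compliance$sd_percent,
            report$compliance$weekly_trend),
    if (!is.null(report$skipped)) paste("skipped:", report$skipped))
  writeLines(lines, con)
  invisible(c(paths, con))
}

#' @export
print.study_report <- function(x, ...) {
  cat("== Criterion 1: reliability ==\n")
  print(x$reliability, row.names = FALSE, digits = 3)
  cat("\n== Criterion 2: convergence ==\n")
  print(x$convergence, row.names = FALSE, digits = 3)
  cat("\n== Criterion 3: sensitivity to change ==\n")
  print(x$effects, row.names = FALSE, digits = 3)
  if (!is.null(x$skipped)) cat("   note:", x$skipped, "\n")
  cat("\n== Criterion 4: criterion validity ==\n")
  print(x$criterion, row.names = FALSE, digits = 3)
  cat(sprintf("\ncompliance: mean %.1f%% (SD %.1f%%), weekly trend %+.4f\n",
              x$compliance$mean_percent, x$compliance$sd_percent,
              x$compliance$weekly_trend))
  invisible(x)
}
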