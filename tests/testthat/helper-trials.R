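# shared fixtures: small trials with negligible scale censoring, so the
# linear-Gaussian oracles apply without attenuation from clipping
lowcens_truth <- function(...) {
  args <- list(gamma00 = 50, gamma10 = -0.1, gamma01 = 0, gamma11 = -0.2,
               tau00 = 100, tau11 = 0.16, tau01 = -0.8, sigma2 = 225,
               change_cor = 0.4, trait_state_cor = 0.5,
               compliance_base = 0.78, compliance_weekly_decline = 0.03)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(truth_params, args)
}

quiet_sim <- function(design, truth, seed) {
  suppressWarnings(simulate_trial(design, truth, seed))
}

quiet_lmm <- function(...) suppressWarnings(fit_random_slope_lmm(...))

# mean per-beep compliance over the trial, for the design oracle
mean_compliance <- function(design, truth) {
  wk <- schedule_weeks(design)
  mean(truth$compliance_base - truth$compliance_weekly_decline * wk)
}

schedule_weeks <- function(design) {
  rep((seq_len(design$duration_days) - 1L) %/% 7L,
      each = design$beeps_per_day)
}
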