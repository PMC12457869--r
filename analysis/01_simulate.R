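#!/usr/bin/env Rscript
# Step 1: generate the two demonstration trials.
#
# Two synthetic studies bracket the designs this pipeline targets:
#   * a 2-arm adolescent/college-style trial: 21 days x 3 beeps on a 0-100
#     momentary scale, 13-item 0-4 questionnaire, 4 depression waves;
#   * a single-arm adult-style trial: 28 days x 4 beeps on a 1-7 scale,
#     15-item questionnaire, pre/post depression only.
# Both are written as plain CSV under results/data/ together with the
# ground-truth record (true intercepts, slopes, latent traits) that later
# steps use for parameter-recovery checks.

library(emapsych)

out_root <- "results/data"
for (name in c("care", "hmp")) {
  cfg <- read_study_config(
    system.file("extdata", paste0("demo-", name, ".yaml"),
                package = "emapsych"))
  trial <- suppressWarnings(
    simulate_trial(cfg$synthetic$design, cfg$synthetic$truth,
                   seed = cfg$sim_seed))
  dir <- file.path(out_root, name)
  write_sim_trial(trial, dir)
  cat(sprintf(
    "%s-like trial: %d participants, %d EMA observations (%.1f%% of scheduled), %d waves\n",
    toupper(name), cfg$synthetic$design$n_participants, nrow(trial$ema),
    100 * nrow(trial$ema) /
      (cfg$synthetic$design$n_participants *
         cfg$synthetic$design$duration_days *
         cfg$synthetic$design$beeps_per_day),
    cfg$synthetic$design$depression_waves))
  cat("  written to", dir, "\n")
}
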