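synthetic:
  design:
    n_participants: 92
    n_arms: 1
    duration_days: 28
    beeps_per_day: 4
    ema_scale: [1, 7]
    n_items_t: 15
    item_scale: [0, 4]
    depression_waves: 2
  truth:
    gamma00: 4.4
    gamma10: -0.012
    gamma01: 0
    gamma11: 0
    tau00: 1.2
    tau11: 0.004
    tau01: -0.02
    sigma2: 1.5
    trait_noise_sd: 0.7
    change_cor: 0.35
    trait_state_cor: 0.45
    compliance_base: 0.84
    compliance_weekly_decline: 0.034
    dep_effect_retro: 0.4
    dep_effect_ema: 2.0
window_k: 3
min_obs: 4
split_seed: 19
sim_seed: 202
n_splits: 1
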