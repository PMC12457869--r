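synthetic:
  design:
    n_participants: 320
    n_arms: 2
    duration_days: 21
    beeps_per_day: 3
    ema_scale: [0, 100]
    n_items_t: 13
    item_scale: [0, 4]
    depression_waves: 4
  truth:
    gamma00: 50
    gamma10: -0.1
    gamma01: 0
    gamma11: -0.2
    tau00: 100
    tau11: 0.16
    tau01: -0.8
    sigma2: 225
    change_cor: 0.4
    trait_state_cor: 0.5
    compliance_base: 0.78
    compliance_weekly_decline: 0.03
window_k: 3
min_obs: 4
split_seed: 11
sim_seed: 101
n_splits: 1
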