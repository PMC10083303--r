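fr_value: 1
n_fr1_sessions: 5
n_fr2_sessions: 5
active_period_s: 3300.0
drugfree_period_s: 900.0
timeout_s: 10.0
max_reinforcers: 50
session_cap_s: 7500.0
pr_ratio_series:
- 1
- 5
- 12
- 21
- 33
- 51
- 75
- 90
- 120
- 155
- 180
- 225
- 260
- 300
- 350
- 410
- 465
- 540
- 630
- 730
- 850
- 1000
- 1200
- 1500
- 1800
- 2100
- 2400
- 2700
- 3000
- 3400
- 3800
- 4200
- 4600
- 5000
- 5500
pr_cap_s: 14400.0
pr_inactivity_s: 3600.0
shock_session_s: 3000.0
shock_pair_window_s: 60.0
shock_mA: 0.18
extinction_session_s: 7200.0
n_extinction_sessions: 10
reinstatement_total_s: 5400.0
reinstatement_cue_phase_s: 1800.0
house_light_start_s: 3.0
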