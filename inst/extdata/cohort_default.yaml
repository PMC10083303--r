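n_subjects: 60
fraction_vulnerable: 0.3
trait_distributions:
  resilient:
    base_active_rate:
      dist: lnorm
      meanlog: -0.430782916092454
      sdlog: 0.22
    base_inactive_rate:
      dist: lnorm
      meanlog: -2.120263536200091
      sdlog: 0.4
    learning_gain:
      dist: lnorm
      meanlog: 0.587786664902119
      sdlog: 0.12
    impulsivity:
      dist: lnorm
      meanlog: -0.22314355131421
      sdlog: 0.4
    perseverance:
      dist: lnorm
      meanlog: -0.510825623765991
      sdlog: 0.4
    motivation:
      dist: choice
      values:
      - 5.0
      - 12.0
      - 21.0
      - 33.0
    shock_tolerance:
      dist: beta
      shape1: 5.0
      shape2: 5.0
    extinction_decay:
      dist: lnorm
      meanlog: -0.798507696217772
      sdlog: 0.3
    burst_gain:
      dist: lnorm
      meanlog: -1.203972804325936
      sdlog: 0.4
      shift: 1.0
    cue_gain:
      dist: lnorm
      meanlog: -0.693147180559945
      sdlog: 0.4
      shift: 1.0
  vulnerable:
    base_active_rate:
      dist: lnorm
      meanlog: -0.356674943938732
      sdlog: 0.15
    base_inactive_rate:
      dist: lnorm
      meanlog: -2.120263536200091
      sdlog: 0.4
    learning_gain:
      dist: lnorm
      meanlog: 0.78845736036427
      sdlog: 0.1
    impulsivity:
      dist: lnorm
      meanlog: 0.916290731874155
      sdlog: 0.35
    perseverance:
      dist: lnorm
      meanlog: 1.09861228866811
      sdlog: 0.35
    motivation:
      dist: choice
      values:
      - 51.0
      - 75.0
      - 90.0
    shock_tolerance:
      dist: beta
      shape1: 12.0
      shape2: 2.0
    extinction_decay:
      dist: lnorm
      meanlog: -2.120263536200091
      sdlog: 0.3
    burst_gain:
      dist: lnorm
      meanlog: 0.405465108108164
      sdlog: 0.3
      shift: 1.0
    cue_gain:
      dist: lnorm
      meanlog: 0.693147180559945
      sdlog: 0.3
      shift: 1.0
group_levels:
- saline
- cno
group_probs:
- 0.5
- 0.5
dropout_prob: 0.033333333333333
seed: 1
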