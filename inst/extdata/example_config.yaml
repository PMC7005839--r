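# Example pipeline configuration: a small two-group synthetic cohort.
# Each trait is (location, scale): lognormal (meanlog, sdlog) for rates,
# the persistence factor and the motivation cap; logit-normal for the
# shock-continuation probability. The protocol is shortened to the
# sessions the criterion scores depend on (persistence is scored on the
# last 3 FR5 sessions before the progressive-ratio test).
groups:
  control:
    "n": 24
  vulnerable:
    "n": 24
    persistence_factor: [0.2231436, 0.5]   # log(1.25)
    motivation_cap: [6.3969297, 0.6]       # log(600)
    shock_continue_prob: [1.0986123, 0.8]  # qlogis(0.75)
protocol:
  n_fr1: 3
  n_fr5: 4
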