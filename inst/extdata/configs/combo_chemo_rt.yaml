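# Combination: docetaxel 0.132 g Q3W from day 0 + fractionated radiotherapy
# (2.5 Gy, 5 d/wk for 2 weeks from day 10).
lattice:
  extents: [20, 20, 20]
init:
  n_cancer: 120
rates:
  division: 0.008
treatments:
  - modality: docetaxel
    amount: 0.132
    pattern: q3w
    start_day: 0
    n_doses: 2
  - modality: radiation
    amount: 2.5
    pattern: fractionated
    start_day: 10
    weeks: 2
    days_per_week: 5
run:
  horizon_days: 30
  seed: 1
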