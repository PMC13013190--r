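# Combination: weekly DDRi from day 7 + fractionated radiotherapy
# (2.5 Gy, 5 d/wk for 2 weeks from day 14).
lattice:
  extents: [20, 20, 20]
init:
  n_cancer: 150
rates:
  division: 0.008
treatments:
  - modality: ddri
    amount: 210
    pattern: weekly
    start_day: 7
    n_doses: 3
  - modality: radiation
    amount: 2.5
    pattern: fractionated
    start_day: 14
    weeks: 2
    days_per_week: 5
run:
  horizon_days: 30
  seed: 1
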