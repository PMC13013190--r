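# Fractionated radiotherapy 2.5 Gy, 5 days/week for 2 weeks from day 4
# (reduced-horizon analogue of the 2.5 Gy x 5 d/wk x 6-7 wk arm).
lattice:
  extents: [20, 20, 20]
init:
  n_cancer: 400
rates:
  division: 0.004
radio:
  alpha: 0.05
  beta: 0.005
treatments:
  - modality: radiation
    amount: 2.5
    pattern: fractionated
    start_day: 4
    weeks: 2
    days_per_week: 5
run:
  horizon_days: 21
  seed: 1
  output_interval: 6
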