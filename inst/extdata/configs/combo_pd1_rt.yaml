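# Combination: PD1 antibody (2 mg/kg Q3W from day 3) + fractionated
# radiotherapy (2.5 Gy, 5 d/wk for 2 weeks from day 10).
lattice:
  extents: [20, 20, 20]
init:
  n_cancer: 120
treatments:
  - modality: pd1_antibody
    amount: 2
    pattern: q3w
    start_day: 3
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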