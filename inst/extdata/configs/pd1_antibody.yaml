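# PD1 antibody 2 mg/kg Q3W: near-saturating receptor occupancy suppresses
# effector exhaustion (desk-scale analogue of the checkpoint-blockade arm).
lattice:
  extents: [20, 20, 20]
init:
  n_cancer: 80
treatments:
  - modality: pd1_antibody
    amount: 2
    pattern: q3w
    start_day: 7
    n_doses: 2
run:
  horizon_days: 30
  seed: 1
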