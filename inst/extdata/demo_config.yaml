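# Demo pipeline configuration: a small simulated cohort study with one
# single-substrate ROC comparison (UC vs CD on the RSVL cathepsin substrate
# at pH 5.5).
simulation:
  cohorts: {HC: 4, CD: 4, UC: 4, IBS: 3}
  ph_levels: [5.5, 7.5]
  replicates: 3
  seed: 2026
qc:
  type: adaptive
  k: 10
roc_comparisons:
  - {cohort_a: UC, cohort_b: CD, substrate_id: RSVL-AMC, ph: 5.5}
adjust_p: true
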