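# Demo pipeline configuration: small cohort, coarse voxels.
master_seed: 1
stages: [simulate, calibrate, fe, cutpoints, classify, pra, report]
cohort:
  name: astronaut
  n: 8
subject:
  cohort: astronaut
voxel_mm: 5
scanner:
  id: scannerA
  hu_slope: 1.2
  hu_intercept: -15
  noise_sd: 5
flight:
  duration_days: 154
  trabecular_loss_pct_month: 1.5
  cortical_loss_pct_month: 1.0
dxa:
  ref_mean: 2.0
  ref_sd: 0.25
bone_threshold: 200
solve:
  displacement_increment_mm: 0.3
  max_steps: 18
  drop_fraction: 0.05
cutpoints:
  cohort: AGES_fractured
  n: 2000
  percentile: 75
pra:
  n: 100000
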