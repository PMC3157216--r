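# Default feasibility-study configuration: the core grid of lesion
# diameters, placement classes, binding affinities and demyelination folds,
# imaged for 20 min starting 2 h after injection.
seed: 20260101
n_replicates: 8
phantom:
  dim: [160, 160, 80]
  seed: 1
agent:
  kon: 5.5e+05
  logp: 4
  plasma_protein_bound: 0.10
  liver_microsomal_cl: 8.0e-3
  dose_moles: 1.0e-9
grid:
  kd: [1.0e-9, 1.0e-6]
  demyelination_fold: [10, 100]
  diameters_mm: [4, 6, 8, 10]
  placements: [interior_wm, wm_gm_border]
acquisition:
  scan_duration: 1200
  injected_dose: 10
  delay_to_scan: 7200
  half_life: 6588
  positron_yield: 0.97
  scatter_fraction: 0.15
  target_counts: 1.0e+06
analysis:
  thresholds: [1, 2]
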