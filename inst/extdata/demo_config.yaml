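# Demonstration run: a small simulated cohort exercising every stage of the
# pipeline (simulate -> QC -> differential testing -> co-occurrence networks).
seed: 20260101
simulate:
  n_per_condition: {Control: 12, I: 12, II: 12, III: 12, IV: 12}
  n_features: 150
  n_species: 40
  qc_cadence: 10
  n_blanks: 4
  drift_amplitude: 0.3
  noise_cv: 0.10
  planted_diff:
    feature: [1, 2, 3, 4, 5, 6, 7, 8]
    condition: [IV, IV, IV, IV, IV, IV, III, III]
    log2fc: [1.5, 1.5, -1.5, -1.5, 2.0, -2.0, 1.5, -1.5]
  planted_edges:
    species: [1, 2, 3]
    feature: [10, 11, 12]
    rho: [0.8, 0.8, -0.8]
qc:
  span: 0.75
differential:
  fc_min: 2
  fdr: 0.01
  contrasts: [III, IV]
network:
  b_perms: 1000
  r_threshold: 0.3
  p_threshold: 0.05
  min_abundance: 0.01
  min_prevalence: 40
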