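# Example hjdimer run configuration: synthesize a stacked (H-like)
# rigid-rod dimer ensemble, then analyze it with the standard protocol
# strides.  Paths are relative to this file's directory.
synth:
  kind: dimer
  mode: H_dimer
  n_frames: 500
  dt: 100
  seed: 7
  angle_sd_deg: 10
topology: example_synth.pdb
trajectories:
  - path: example_synth.pdb
    format: pdb
    dt: 100
dyes:
  - {label: dye_A, chain: A, resno: 1, resname: CY5,
     end_r: [C1], end_s: [C2], mu_debye: 15.35}
  - {label: dye_C, chain: C, resno: 1, resname: CY5,
     end_r: [C1], end_s: [C2], mu_debye: 15.35}
coupling:
  refractive_index: 1.33
analysis:
  stride_ps: 100
  contact_stride_ps: 500
  burn_in_ps: 0
  cutoff_nm: 1.2
  kappa_boundary: 1.0
  dimer_r_max_nm: 1.5
  window: [11, 16]
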