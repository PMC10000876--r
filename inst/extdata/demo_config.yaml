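# Demo configuration for run_pipeline(): small synthetic cohorts with a
# mutant-like linguo-distal shift of the first cusp, plus a 3D morph of a
# wild-type-like crown toward a mutant-like one.
seed: 1
outdir: odontomorph_out
outlines:
  n_wt: 21
  n_mut: 33
  n_points: 64
  dtheta1: 0.3
  noise_sd: 0.01
analysis:
  n_points: 64
  n_harmonics: 9
  variance_threshold: 0.95
  reduce_sides: false
morphotypes:
  n_wt: 21
  n_mut: 33
morph:
  enabled: true
  resolution: 40
  cusp_shift:
    c9: [-0.12, 0.1]
  boundary_frac: 0.15
  cutoff: 5
  mode: global
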