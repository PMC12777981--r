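# Three-class peptide benchmark: reference 42-mer vs E22G vs G37R,
# moderate noise. Used by the acceptance suite.
task: peptide
n_per_class: 200
seed: 42
params:
  depth_per_volume: 2.0
  dwell_mean_points: 12
  dwell_shape: 400
  noise_sd: 0.08
  out_len: 500
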