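# Eight barcode classes, low noise.
task: barcode8
n_per_class: 30
seed: 7
params:
  noise_sd: 0.02
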