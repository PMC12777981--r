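# Bound vs unbound carriers (random barcodes), low noise.
task: binding2
n_per_class: 60
seed: 11
params:
  noise_sd: 0.02
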