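{
  "n_fluid": 2,
  "n_solid": 3,
  "seed": 7,
  "kernel_length": 5,
  "bands": ["fundamental"],
  "modes": ["B-mode", "SLSC"],
  "write_images": false
}
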