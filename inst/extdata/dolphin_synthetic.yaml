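# Run configuration for the synthetic dolphin-like worked example.
# 12 unequal slabs, 10 subslabs each; whole-body mean density 1027 kg/m^3.
slab_bounds: [0, 0.168, 0.36, 0.576, 0.816, 1.056, 1.296, 1.536, 1.752, 1.944, 2.112, 2.256, 2.4]
n_subslabs: 10
density:
  default: 1027
gdi_slabs: 120
k_range: [2, 2.3]
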