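# Reference two-bead chain (k_B = 1): hot bath 250, cold bath 25.
# Synthetic example configuration for the CLI and model_from_config().
n_beads: 2
k: 1.0
gamma: 1.0
temps:
- 250.0
- 25.0
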