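# Named receptor-ligation scenarios over the four input ligands.
# A: CAR ligation only; B: + IL2; C: + both inhibitory ligands;
# D: PDL1L2 blocked; E: CD8086 blocked.
scenarios:
  A:
    active_inputs: [TAex]
  B:
    active_inputs: [TAex, IL2ex]
  C:
    active_inputs: [TAex, IL2ex, PDL1L2ex, CD8086ex]
  D:
    active_inputs: [TAex, IL2ex, CD8086ex]
  E:
    active_inputs: [TAex, IL2ex, PDL1L2ex]
defaults:
  horizon: 100
  replicates: 10000
  steady_window: 20
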